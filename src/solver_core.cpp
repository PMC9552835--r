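// Time-marching core for the 1D-0D network solver.
//
// Mirrors the R reference implementations in R/junctions.R and R/solver.R:
// Richtmyer two-step Lax-Wendroff interior update, Keller-box boundary
// relations, Newton-Raphson junction systems, Dirichlet inlet and
// Windkessel outlet coupling. All quantities in CGS.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Wave {
  std::vector<double> t, v;
  double T;
  double eval(double tt) const {
    double tm = std::fmod(tt, T);
    if (tm < 0) tm += T;
    // grid is [0, T); wrap the closing value
    size_t n = t.size();
    if (tm <= t[0]) {
      // between the (wrapped) last sample and the first
      double t0 = t[n - 1] - T, v0 = v[n - 1];
      return v0 + (v[0] - v0) * (tm - t0) / (t[0] - t0);
    }
    if (tm >= t[n - 1]) {
      double t1 = t[0] + T, v1 = v[0];
      return v[n - 1] + (v1 - v[n - 1]) * (tm - t[n - 1]) / (t1 - t[n - 1]);
    }
    size_t lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (t[mid] <= tm) lo = mid; else hi = mid;
    }
    return v[lo] + (v[hi] - v[lo]) * (tm - t[lo]) / (t[hi] - t[lo]);
  }
};

Wave as_wave(List w) {
  Wave out;
  NumericVector t = w["time"], v = w["value"];
  out.t.assign(t.begin(), t.end());
  out.v.assign(v.begin(), v.end());
  out.T = as<double>(w["period"]);
  return out;
}

struct Seg {
  int np;            // gridpoints
  double dx, A0, f, alpha, fric, sqrtA0;
  int off;           // offset into the global state arrays
};

struct Sten {
  double av, at, au;
  double Qprev;
};

struct Junc {
  int kind;                    // 0 plain, 1 stenosis
  std::vector<int> parents, children;
  int sten;                    // index into stenosis table or -1
};

struct Outlet {
  int seg;
  double R1, R2, Ct;
  Wave pext;
};

inline double tube_p(const Seg& s, double A, double P0) {
  return s.f * (1.0 - s.sqrtA0 / std::sqrt(A)) + P0;
}
inline double tube_dPdA(const Seg& s, double A) {
  return s.f * s.sqrtA0 / (2.0 * A * std::sqrt(A));
}
inline double area_from_p(const Seg& s, double P, double P0) {
  double x = (P - P0) / s.f;
  if (x >= 1.0) stop("nonphysical pressure at boundary (tube-law collapse)");
  double d = 1.0 - x;
  return s.A0 / (d * d);
}

// dense Gaussian elimination with partial pivoting, n <= 4
void lin_solve(int n, double J[4][4], double r[4], double x[4]) {
  int piv[4] = {0, 1, 2, 3};
  for (int c = 0; c < n; ++c) {
    int best = c;
    for (int k = c + 1; k < n; ++k)
      if (std::fabs(J[piv[k]][c]) > std::fabs(J[piv[best]][c])) best = k;
    std::swap(piv[c], piv[best]);
    double d = J[piv[c]][c];
    if (d == 0.0) stop("singular junction Jacobian");
    for (int k = c + 1; k < n; ++k) {
      double m = J[piv[k]][c] / d;
      for (int c2 = c; c2 < n; ++c2) J[piv[k]][c2] -= m * J[piv[c]][c2];
      r[piv[k]] -= m * r[piv[c]];
    }
  }
  for (int c = n - 1; c >= 0; --c) {
    double s = r[piv[c]];
    for (int c2 = c + 1; c2 < n; ++c2) s -= J[piv[c]][c2] * x[c2];
    x[c] = s / J[piv[c]][c];
  }
}

struct Port {
  const Seg* seg;
  bool parent;       // parent: right end, slope -dx/dt; child: left end
  double slope, icpt;
  double A;          // iterate
};

}  // namespace

// [[Rcpp::export(name = ".core_run")]]
List core_run(List segments, List junctions, List outlets, List inlet_w,
              double P0, double rho, double T, int n_cycles, int samples,
              double dt0, double cfl_safety, int root,
              double newton_tol, int newton_maxit,
              double outlet_tol, int outlet_maxit) {
  // ---- unpack ----
  int ns = segments.size();
  std::vector<Seg> seg(ns);
  int total = 0;
  for (int i = 0; i < ns; ++i) {
    List s = segments[i];
    seg[i].np = as<int>(s["np"]);
    seg[i].dx = as<double>(s["dx"]);
    seg[i].A0 = as<double>(s["A0"]);
    seg[i].f = as<double>(s["f"]);
    seg[i].alpha = as<double>(s["alpha"]);
    seg[i].fric = as<double>(s["fric"]);
    seg[i].sqrtA0 = std::sqrt(seg[i].A0);
    seg[i].off = total;
    total += seg[i].np;
  }
  std::vector<Junc> junc(junctions.size());
  std::vector<Sten> stens;
  for (int i = 0; i < (int)junctions.size(); ++i) {
    List j = junctions[i];
    IntegerVector p = j["parents"], c = j["children"];
    junc[i].parents.assign(p.begin(), p.end());
    junc[i].children.assign(c.begin(), c.end());
    junc[i].sten = -1;
    if (!Rf_isNull(j["sten"])) {
      List st = j["sten"];
      Sten s {as<double>(st["av"]), as<double>(st["at"]),
              as<double>(st["au"]), 0.0};
      stens.push_back(s);
      junc[i].sten = stens.size() - 1;
    }
  }
  std::vector<Outlet> outs(outlets.size());
  for (int i = 0; i < (int)outlets.size(); ++i) {
    List o = outlets[i];
    outs[i].seg = as<int>(o["seg"]);
    outs[i].R1 = as<double>(o["R1"]);
    outs[i].R2 = as<double>(o["R2"]);
    outs[i].Ct = as<double>(o["Ct"]);
    outs[i].pext = as_wave(o["pext"]);
  }
  Wave inlet = as_wave(inlet_w);

  // ---- state ----
  std::vector<double> A(total), Q(total, 0.0), An(total), Qn(total);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < seg[i].np; ++k) A[seg[i].off + k] = seg[i].A0;
  // inlet initial pressure may differ from P0; keep A = A0 (the stated IC)

  // outlet previous-step P, Q
  std::vector<double> outP(outs.size()), outQ(outs.size(), 0.0);
  for (size_t i = 0; i < outs.size(); ++i) outP[i] = P0;

  int nsamp_total = n_cycles * samples;
  NumericMatrix Asamp(total, nsamp_total), Qsamp(total, nsamp_total);
  NumericVector tsamp(nsamp_total);
  IntegerVector newton_max(1, 0), outlet_max(1, 0);
  NumericVector dt_cycle(n_cycles);

  // scratch
  std::vector<double> Ah, Qh, F2h, Sh;

  double dt = dt0;
  double tglobal = 0.0;

  auto cfl_bound = [&]() {
    double b = R_PosInf;
    for (int i = 0; i < ns; ++i) {
      const Seg& s = seg[i];
      for (int k = 0; k < s.np; ++k) {
        double a = A[s.off + k];
        double c = std::sqrt(s.f / (2.0 * rho)) * std::pow(a / s.A0, 0.25);
        double v = std::fabs(Q[s.off + k]) / a;
        double bb = s.dx / (v + c);
        if (bb < b) b = bb;
      }
    }
    return b;
  };

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // re-evaluate the CFL bound with the current state; shrink dt if needed
    double bound = cfl_safety * cfl_bound();
    if (bound < dt) dt = bound;
    int steps = (int)std::ceil(T / dt);
    dt = T / steps;
    dt_cycle[cyc] = dt;

    int next_samp = 0;
    for (int n = 0; n < steps; ++n) {
      if (next_samp < samples &&
          n == (int)std::floor((double)next_samp * steps / samples + 0.5)) {
        int col = cyc * samples + next_samp;
        for (int k = 0; k < total; ++k) {
          Asamp(k, col) = A[k];
          Qsamp(k, col) = Q[k];
        }
        tsamp[col] = tglobal;
        // mid-run stability check at sample resolution
        if (cfl_bound() < dt)
          stop("CFL condition violated mid-run (cycle %d)", cyc + 1);
        ++next_samp;
      }

      // ---- interior Lax-Wendroff update ----
      for (int i = 0; i < ns; ++i) {
        const Seg& s = seg[i];
        int M = s.np - 1;
        Ah.resize(M); Qh.resize(M); F2h.resize(M); Sh.resize(M);
        double lam = dt / s.dx;
        double cf = s.f / rho * s.sqrtA0;
        const double* Ai = &A[s.off];
        const double* Qi = &Q[s.off];
        for (int k = 0; k < M; ++k) {
          double F2l = s.alpha * Qi[k] * Qi[k] / Ai[k] + cf * std::sqrt(Ai[k]);
          double F2r = s.alpha * Qi[k + 1] * Qi[k + 1] / Ai[k + 1] +
            cf * std::sqrt(Ai[k + 1]);
          double Aav = 0.5 * (Ai[k] + Ai[k + 1]);
          double Qav = 0.5 * (Qi[k] + Qi[k + 1]);
          double Sav = -s.fric * Qav / Aav;
          Ah[k] = Aav - 0.5 * lam * (Qi[k + 1] - Qi[k]);
          Qh[k] = Qav - 0.5 * lam * (F2r - F2l) + 0.5 * dt * Sav;
          if (Ah[k] <= 0.0)
            stop("negative area in half-step (segment %d)", i + 1);
          F2h[k] = s.alpha * Qh[k] * Qh[k] / Ah[k] + cf * std::sqrt(Ah[k]);
          Sh[k] = -s.fric * Qh[k] / Ah[k];
        }
        double* Ao = &An[s.off];
        double* Qo = &Qn[s.off];
        Ao[0] = Ai[0]; Qo[0] = Qi[0];
        Ao[M] = Ai[M]; Qo[M] = Qi[M];
        for (int k = 1; k < M; ++k) {
          Ao[k] = Ai[k] - lam * (Qh[k] - Qh[k - 1]);
          Qo[k] = Qi[k] - lam * (F2h[k] - F2h[k - 1]) +
            0.5 * dt * (Sh[k] + Sh[k - 1]);
          if (Ao[k] <= 0.0 || !std::isfinite(Ao[k]) || !std::isfinite(Qo[k]))
            stop("numerical instability (segment %d, step %d)", i + 1, n + 1);
        }
      }

      double tnew = tglobal + dt;

      // ---- inlet (Dirichlet pressure at root x0) ----
      {
        const Seg& s = seg[root];
        double Pin = inlet.eval(tnew);
        double Anew = area_from_p(s, Pin, P0);
        double r = s.dx / dt;
        const double* Ai = &A[s.off];
        const double* Qi = &Q[s.off];
        double icpt = -r * (Ai[0] + Ai[1] - An[s.off + 1]) -
          Qi[0] + Qi[1] + Qn[s.off + 1];
        An[s.off] = Anew;
        Qn[s.off] = r * Anew + icpt;
      }

      // ---- junctions ----
      for (size_t ji = 0; ji < junc.size(); ++ji) {
        Junc& j = junc[ji];
        int np = j.parents.size(), nc = j.children.size();
        int m = np + nc;
        Port ports[4];
        for (int k = 0; k < np; ++k) {
          const Seg& s = seg[j.parents[k]];
          int M = s.np - 1;
          double r = s.dx / dt;
          const double* Ai = &A[s.off];
          const double* Qi = &Q[s.off];
          ports[k].seg = &s;
          ports[k].parent = true;
          ports[k].slope = -r;
          ports[k].icpt = r * (Ai[M] + Ai[M - 1] - An[s.off + M - 1]) -
            Qi[M] + Qi[M - 1] + Qn[s.off + M - 1];
          ports[k].A = Ai[M];
        }
        for (int k = 0; k < nc; ++k) {
          const Seg& s = seg[j.children[k]];
          double r = s.dx / dt;
          const double* Ai = &A[s.off];
          const double* Qi = &Q[s.off];
          Port& p = ports[np + k];
          p.seg = &s;
          p.parent = false;
          p.slope = r;
          p.icpt = -r * (Ai[0] + Ai[1] - An[s.off + 1]) -
            Qi[0] + Qi[1] + Qn[s.off + 1];
          p.A = Ai[0];
        }
        Sten* st = (j.sten >= 0) ? &stens[j.sten] : nullptr;

        // Newton-Raphson on the m end areas
        double qs = 0.0;
        for (int k = 0; k < m; ++k)
          qs += std::fabs(ports[k].slope * ports[k].A + ports[k].icpt);
        double scale_q = std::max(1.0, qs);
        double scale_p = std::max({1.0,
          std::fabs(tube_p(*ports[0].seg, ports[0].A, P0)),
          ports[0].seg->f});

        int it = 0;
        double r[4], J[4][4], dx_[4];
        for (;;) {
          ++it;
          double Qv[4], Pv[4], phi[4];
          for (int k = 0; k < m; ++k) {
            Qv[k] = ports[k].slope * ports[k].A + ports[k].icpt;
            Pv[k] = tube_p(*ports[k].seg, ports[k].A, P0);
            double v = Qv[k] / ports[k].A;
            phi[k] = Pv[k] + 0.5 * rho * v * v;
          }
          double dPs = 0.0, ddPs_dQ = 0.0;
          if (st) {
            dPs = st->av * Qv[0] + st->at * Qv[0] * std::fabs(Qv[0]) +
              st->au * (Qv[0] - st->Qprev) / dt;
            ddPs_dQ = st->av + 2.0 * st->at * std::fabs(Qv[0]) + st->au / dt;
          }
          r[0] = 0.0;
          for (int k = 0; k < m; ++k)
            r[0] += (ports[k].parent ? Qv[k] : -Qv[k]);
          double rmax = std::fabs(r[0]) / scale_q;
          for (int a = 1; a < m; ++a) {
            r[a] = phi[0] - phi[a] - (st ? dPs : 0.0);
            rmax = std::max(rmax, std::fabs(r[a]) / scale_p);
          }
          if (rmax < newton_tol) break;
          if (it > newton_maxit)
            stop("junction Newton failed to converge (junction %d, step %d)",
                 (int)ji + 1, n + 1);
          for (int a = 0; a < m; ++a)
            for (int b = 0; b < m; ++b) J[a][b] = 0.0;
          double dphi[4];
          for (int k = 0; k < m; ++k) {
            double dQ = ports[k].slope;
            double Ak = ports[k].A;
            dphi[k] = tube_dPdA(*ports[k].seg, Ak) +
              rho * (Qv[k] * dQ / (Ak * Ak) - Qv[k] * Qv[k] / (Ak * Ak * Ak));
            J[0][k] = (ports[k].parent ? dQ : -dQ);
          }
          for (int a = 1; a < m; ++a) {
            J[a][0] = dphi[0];
            J[a][a] -= dphi[a];
            if (st) J[a][0] -= ddPs_dQ * ports[0].slope;
          }
          double nr[4];
          for (int a = 0; a < m; ++a) nr[a] = -r[a];
          lin_solve(m, J, nr, dx_);
          double lamd = 1.0;
          for (int tries = 0; tries < 60; ++tries) {
            bool ok = true;
            for (int k = 0; k < m; ++k)
              if (ports[k].A + lamd * dx_[k] <= 0.0) { ok = false; break; }
            if (ok) break;
            lamd *= 0.5;
          }
          for (int k = 0; k < m; ++k) ports[k].A += lamd * dx_[k];
        }
        if (it > newton_max[0]) newton_max[0] = it;

        // write back the solved endpoint states
        for (int k = 0; k < np; ++k) {
          const Seg& s = seg[j.parents[k]];
          An[s.off + s.np - 1] = ports[k].A;
          Qn[s.off + s.np - 1] = ports[k].slope * ports[k].A + ports[k].icpt;
        }
        for (int k = 0; k < nc; ++k) {
          const Seg& s = seg[j.children[k]];
          An[s.off] = ports[np + k].A;
          Qn[s.off] = ports[np + k].slope * ports[np + k].A +
            ports[np + k].icpt;
        }
        if (st)
          st->Qprev = ports[0].slope * ports[0].A + ports[0].icpt;
      }

      // ---- outlets ----
      for (size_t oi = 0; oi < outs.size(); ++oi) {
        Outlet& o = outs[oi];
        const Seg& s = seg[o.seg];
        int M = s.np - 1;
        double r = s.dx / dt;
        const double* Ai = &A[s.off];
        const double* Qi = &Q[s.off];
        double slope = -r;
        double icpt = r * (Ai[M] + Ai[M - 1] - An[s.off + M - 1]) -
          Qi[M] + Qi[M - 1] + Qn[s.off + M - 1];
        double Pext_n = o.pext.eval(tglobal);
        double Pext_np1 = o.pext.eval(tnew);
        double kk = dt / (o.R1 * o.R2 * o.Ct);
        double Pn = outP[oi], Qold = outQ[oi];
        double qwk_const = Qold + kk * Pn - kk * (o.R1 + o.R2) * Qold -
          Pn / o.R1 - (Pext_np1 - Pext_n) / o.R1 - kk * Pext_n;
        double P = Pn, lo = NA_REAL, hi = NA_REAL;
        bool has_lo = false, has_hi = false;
        int it = 0;
        double Pmax = P0 + 0.999 * s.f;
        for (;;) {
          ++it;
          double Acur = area_from_p(s, P, P0);
          double hres = (slope * Acur + icpt) - (P / o.R1 + qwk_const);
          if (hres > 0) { lo = has_lo ? std::max(lo, P) : P; has_lo = true; }
          if (hres < 0) { hi = has_hi ? std::min(hi, P) : P; has_hi = true; }
          double x = (P - P0) / s.f;
          double dA = 2.0 * s.A0 / (s.f * std::pow(1.0 - x, 3));
          double dh = slope * dA - 1.0 / o.R1;
          double Pn1 = P - hres / dh;
          if (has_lo && has_hi && (Pn1 <= lo || Pn1 >= hi))
            Pn1 = 0.5 * (lo + hi);
          if (Pn1 >= Pmax) Pn1 = 0.5 * (P + Pmax);
          if (std::fabs(Pn1 - P) < outlet_tol) { P = Pn1; break; }
          if (it > outlet_maxit)
            stop("outlet coupling failed to converge (outlet %d, step %d)",
                 (int)oi + 1, n + 1);
          P = Pn1;
        }
        if (it > outlet_max[0]) outlet_max[0] = it;
        double Acur = area_from_p(s, P, P0);
        An[s.off + M] = Acur;
        Qn[s.off + M] = slope * Acur + icpt;
        outP[oi] = P;
        outQ[oi] = Qn[s.off + M];
      }

      std::swap(A, An);
      std::swap(Q, Qn);
      tglobal = tnew;
    }
  }

  return List::create(
    _["A"] = Asamp, _["Q"] = Qsamp, _["time"] = tsamp,
    _["dt_cycle"] = dt_cycle,
    _["newton_max_iterations"] = newton_max[0],
    _["outlet_max_iterations"] = outlet_max[0]);
}
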