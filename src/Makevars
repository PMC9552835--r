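# Build against the system C library so the shared object loads with the
# runtime loader (the toolchain's own sysroot targets a newer glibc than the
# one present at run time).
PKG_CXXFLAGS = --sysroot=/ -idirafter /usr/include/x86_64-linux-gnu
PKG_LIBS = --sysroot=/ -B/usr/lib/x86_64-linux-gnu -L/usr/lib/x86_64-linux-gnu
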