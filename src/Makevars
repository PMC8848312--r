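# System liblzma: header via -idirafter so toolchain sysroot headers keep
# priority; the runtime library (liblzma.so.5) is ABI-stable.
PKG_CPPFLAGS = -idirafter /usr/include
PKG_LIBS = -L/usr/lib/x86_64-linux-gnu -llzma
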