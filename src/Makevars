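# GLPK ships with the same conda prefix that provides R itself
# (R_HOME = <prefix>/lib/R), so locate headers and library relative to it.
CONDA_PREFIX_DIR = $(R_HOME)/../..
PKG_CPPFLAGS = -I$(CONDA_PREFIX_DIR)/include
PKG_LIBS = -L$(CONDA_PREFIX_DIR)/lib -Wl,-rpath,$(CONDA_PREFIX_DIR)/lib -lglpk
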