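# drop class and bookkeeping attributes, keeping only the bare array
sfs_array <- function(s) array(as.numeric(unclass(s)), dim = dim(s))
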