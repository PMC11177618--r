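## internal helpers

## scoped seeding: sets the RNG for the remainder of the calling
## function and restores the caller's RNG state on exit
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed))
    withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible()
}

## derive a reproducible child seed from a base seed and a stream index
## (arithmetic in double: exact below 2^53, result always < 2^31)
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9973) %%
               2147483647)
}
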