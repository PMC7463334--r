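# Shared configuration for the analysis scripts. Every script regenerates
# what it needs from this one root seed (the generator draws each stage
# from a named substream, so stages reproduce independently); genotypes
# are additionally written to VCF in 01 and re-read downstream to exercise
# the interchange formats.

library(reefscape)

ROOT_SEED <- as.integer(Sys.getenv("REEFSCAPE_SEED", "1"))
RESULTS <- "results"
CONFIG <- seascape_config(seed = ROOT_SEED)
dir.create(RESULTS, showWarnings = FALSE)

res_path <- function(...) file.path(RESULTS, ...)
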