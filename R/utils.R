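#' @importFrom stats rpois runif rbinom rnorm rexp rgamma lm coef pchisq phyper
#' @importFrom stats dist hclust setNames complete.cases
#' @importFrom utils head read.table write.table
NULL

# Stop with a consistent error class so callers/tests can distinguish
# argument misuse from data-integrity problems.
abort <- function(msg, class) {
  stop(structure(class = c(class, "mutmapr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_param <- function(msg) abort(msg, "mutmapr_parameter_error")
stop_integrity <- function(msg) abort(msg, "mutmapr_integrity_error")
stop_constraint <- function(msg) abort(msg, "mutmapr_constraint_error")
stop_simulation <- function(msg) abort(msg, "mutmapr_simulation_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# Round half away from zero (base round() rounds half to even, which would
# turn 92.45 into 92.4 instead of the printed-style 92.5).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

pct <- function(num, den, digits = 1) {
  if (den == 0) return(0)
  round_half_up(100 * num / den, digits)
}

# Run `expr` under a fixed seed when one is given, restoring the caller's
# RNG state afterwards; with seed = NULL the global stream is used as-is.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
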