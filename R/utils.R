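# Internal helpers: classed conditions and small numeric utilities.

stop_config <- function(msg, call. = FALSE) {
  stop(structure(class = c("epinet_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_data <- function(msg) {
  stop(structure(class = c("epinet_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_format <- function(msg) {
  stop(structure(class = c("epinet_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_pedigree <- function(msg) {
  stop(structure(class = c("epinet_pedigree_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean-impute missing dosages, column-wise. Columns that are entirely
# missing become the constant 0 (they are flagged downstream as
# non-informative rather than erroring here).
impute_mean <- function(dosage) {
  if (!anyNA(dosage)) return(dosage)
  cm <- colMeans(dosage, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- cm[idx[, 2L]]
  dosage
}

# Derive a stream-specific 32-bit seed from a master seed without
# consuming the global RNG state.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}
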