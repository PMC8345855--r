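# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed configuration error naming the offending field
#' @noRd
config_error <- function(field, msg) {
  stop(structure(
    class = c("tbi_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, msg),
         call = NULL, field = field)
  ))
}

data_error <- function(msg) {
  stop(structure(
    class = c("tbi_data_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

check_prob <- function(x, field, n = 1L) {
  if (!is.numeric(x) || length(x) != n || anyNA(x) || any(x < 0) || any(x > 1))
    config_error(field, sprintf("must be %d probabilit%s in [0, 1]",
                                n, if (n == 1L) "y" else "ies"))
  invisible(x)
}

check_pos_int <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    config_error(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

# Canonical time point codes, ordered chronologically.
TIMEPOINTS <- c("preh", "ref_arr", "study_arr", "ed_disch")

TIMEPOINT_LABELS <- c(
  preh      = "pre-hospital",
  ref_arr   = "referring-hospital ED arrival",
  study_arr = "study-hospital ED arrival",
  ed_disch  = "ED discharge"
)

STRATA <- c("ed", "hosp", "icu")

#' Draw one ordinal observation per row from a proportional-odds model
#'
#' @param lp linear predictor (higher = better outcome, i.e. higher category)
#' @param cutpoints strictly increasing cutpoints, length K-1
#' @return integer vector in 1..K
#' @noRd
draw_prop_odds <- function(lp, cutpoints) {
  n <- length(lp)
  k1 <- length(cutpoints)
  # P(Y <= k) = plogis(cutpoints[k] - lp)
  cum <- stats::plogis(outer(lp, cutpoints, function(l, c) c - l))
  u <- stats::runif(n)
  1L + rowSums(u > cum)
}

# Deterministic sub-seed derivation: keeps all derived seeds < 2^31 and
# well-separated for nearby master seeds.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
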