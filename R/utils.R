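# Shared constants and small helpers.

# Canonical order of the four functional categories; bit i of a membership
# mask refers to CATEGORY_NAMES[i] (FMRP_TARGET = 1, MTOR_NETWORK = 2,
# MTOR_MODULATED = 4, VITD_SENSITIVE = 8).
CATEGORY_NAMES <- c("FMRP_TARGET", "MTOR_NETWORK", "MTOR_MODULATED",
                    "VITD_SENSITIVE")

# Confidence-tier vocabulary of SFARI-style scored candidate tables.
# "S" (syndromic) is also accepted as a flag suffix ("2S") orthogonal to
# the numeric tier.
TIER_VOCABULARY <- c(as.character(1:7), "S")
HIGH_TIERS <- c("1", "2", "3")

# STRING-style evidence channels that feed the combined score, plus the
# auxiliary homology channel (reported alongside, never combined).
EVIDENCE_CHANNELS <- c("neighborhood", "fusion", "cooccurrence",
                       "coexpression", "experimental", "database",
                       "textmining")
AUX_CHANNELS <- "homology"

# Fixed precedence used to break ties between equally scoring qualifying
# channels when labeling an edge.
CHANNEL_PRECEDENCE <- c("database", "experimental", "homology", "textmining",
                        "coexpression", "neighborhood", "fusion",
                        "cooccurrence")

WEAKEST_LABEL <- "weakest_high_confidence"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Integer percentage with half-up rounding
#'
#' Computes `100 * num / den` rounded half-up to the nearest integer, the
#' rounding convention used for all reported percentages (e.g. 606/1053
#' gives 58, 179/281 gives 64, 222/281 gives 79). A zero denominator
#' yields 0 rather than an error so empty inputs summarize cleanly.
#'
#' @param num,den Numerator and denominator (non-negative scalars).
#' @return An integer percentage.
#' @export
#' @examples
#' percent_half_up(606, 1053)
#' percent_half_up(179, 281)
percent_half_up <- function(num, den) {
  stopifnot(is.numeric(num), is.numeric(den), length(num) == length(den))
  out <- ifelse(den == 0, 0L, as.integer(floor(100 * num / den + 0.5)))
  out
}

# Order keys numerically where they are all-numeric strings, otherwise
# lexicographically; surrogate symbol keys sort after numeric ids.
key_order <- function(keys) {
  num <- suppressWarnings(as.numeric(keys))
  order(is.na(num), num, keys)
}

sort_keys <- function(keys) keys[key_order(keys)]

# Surrogate keys stand in for symbols the synonym table cannot resolve.
surrogate_key <- function(symbol) {
  if (length(symbol) == 0) return(character(0))
  paste0("SYM:", toupper(trimws(symbol)))
}
is_surrogate_key <- function(key) startsWith(key, "SYM:")

# Membership-mask helpers -----------------------------------------------

# A mask is an integer 0..15; its bitstring form is written in category
# order FMRP_TARGET, MTOR_NETWORK, MTOR_MODULATED, VITD_SENSITIVE, so
# mask 1 is "1000" and mask 15 is "1111".
mask_bits <- function(mask) {
  stopifnot(all(mask >= 0 & mask <= 15))
  vapply(mask, function(m) {
    paste0(as.integer(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), collapse = "")
  }, character(1))
}

bits_to_mask <- function(bits) {
  stopifnot(all(nchar(bits) == 4), all(grepl("^[01]{4}$", bits)))
  vapply(bits, function(b) {
    sum(as.integer(strsplit(b, "")[[1]]) * c(1L, 2L, 4L, 8L))
  }, integer(1), USE.NAMES = FALSE)
}

#' Human-readable label for a membership mask
#'
#' @param mask Integer mask(s) in 0..15.
#' @return Character labels such as `"FMRP_TARGET+VITD_SENSITIVE"`;
#'   mask 0 is labelled `"(none)"`.
#' @export
mask_label <- function(mask) {
  vapply(mask, function(m) {
    if (m == 0) return("(none)")
    paste0(CATEGORY_NAMES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L],
           collapse = "+")
  }, character(1))
}

# Deterministic per-stage substream seed derived from one user seed.
# Kept below 2^31 so it is always a valid R integer.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 1103L + h * 12347L) %% 2147483587L)
}

abort_stage <- function(stage, cause) {
  stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(cause)),
       call. = FALSE)
}
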