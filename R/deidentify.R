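#' De-identification configuration
#'
#' @param shift_range_days Half-width of the coherent date-shift range:
#'   one offset per patient is drawn uniformly from
#'   `[-shift_range_days, +shift_range_days]` (zero included — excluding
#'   it would itself leak information) and applied to all of the
#'   patient's statement dates, so every intra-patient interval is
#'   preserved exactly.
#' @param rare_threshold Minimum number of distinct patients a code
#'   must occur in, source-wide, for its statements to survive (rare
#'   diseases and orphan drugs are identifying).
#' @param seed Integer key for pseudonyms and offsets; the same records
#'   and seed give identical output, different seeds give unlinkable
#'   pseudonyms.
#' @return A `deid_config` list.
#' @export
deid_config <- function(shift_range_days = 30, rare_threshold = 5, seed = 1) {
  stopifnot(shift_range_days >= 1, rare_threshold >= 1)
  structure(list(shift_range_days = as.integer(shift_range_days),
                 rare_threshold = as.integer(rare_threshold),
                 seed = as.integer(seed)),
            class = "deid_config")
}

hash32_hex <- function(key) {
  h <- fnv1a32(key)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

pseudonymize_ids <- function(ids, seed, source_id = "") {
  h <- vapply(ids, function(id) {
    paste0("anon-", hash32_hex(paste(seed, source_id, id, sep = "\x01")))
  }, "")
  # enforce injectivity: salt colliding keys until unique
  salt <- 0L
  while (anyDuplicated(h)) {
    salt <- salt + 1L
    dup <- duplicated(h) | duplicated(h, fromLast = TRUE)
    h[dup] <- vapply(ids[dup], function(id) {
      paste0("anon-", hash32_hex(paste(seed, source_id, id, salt, sep = "\x01")))
    }, "")
    if (salt > 32L) {
      abort("pseudonym collision could not be resolved",
            class = "casechar_integrity_error")
    }
  }
  unname(h)
}

#' De-identify a cohort before it leaves the care zone
#'
#' Applies the privacy transforms expected of EHR data released for
#' safety analysis: patient identifiers are replaced by keyed
#' pseudonyms (stable within a run, unlinkable across seeds); birth
#' dates are already generalized to birth year in the common model;
#' all of a patient's statement dates are shifted coherently by one
#' random per-patient offset so within-patient intervals — and hence
#' any interval-based eligibility result — are unchanged; statements
#' whose code occurs in fewer than `rare_threshold` distinct patients
#' source-wide are removed. The audit summary reports removal counts
#' and the offset distribution, never per-patient offsets.
#'
#' @param x A [cohort()].
#' @param config A [deid_config()].
#' @param source_id Source tag mixed into the pseudonym key.
#' @return List with `cohort` (de-identified) and `audit` (list).
#' @export
deidentify <- function(x, config = deid_config(), source_id = "") {
  p <- x$patients
  s <- x$statements
  # rare-code elimination (statement-level, counted before pseudonymization)
  coded <- filter(s, !is.na(.data$code))
  support <- coded |>
    distinct(.data$scheme, .data$code, .data$patient_id) |>
    count(.data$scheme, .data$code, name = "n_patients")
  rare <- filter(support, .data$n_patients < config$rare_threshold)
  is_rare <- !is.na(s$code) &
    paste(s$scheme, s$code) %in% paste(rare$scheme, rare$code)
  n_removed <- sum(is_rare)
  s <- s[!is_rare, ]
  # keyed pseudonyms
  pseudo <- pseudonymize_ids(p$patient_id, config$seed, source_id)
  key <- stats::setNames(pseudo, p$patient_id)
  p$patient_id <- unname(key[p$patient_id])
  s$patient_id <- unname(key[s$patient_id])
  # coherent per-patient date shift
  withr::with_seed(stream_seed(config$seed, "date-shift"), {
    offsets <- sample(seq(-config$shift_range_days, config$shift_range_days),
                      size = nrow(p), replace = TRUE)
  })
  off <- stats::setNames(offsets, p$patient_id)
  shift <- off[s$patient_id]
  s$start <- s$start + shift
  s$end <- s$end + shift
  audit <- list(
    n_patients = nrow(p),
    n_statements = nrow(s),
    n_statements_removed_rare = n_removed,
    n_rare_codes = nrow(rare),
    rare_threshold = config$rare_threshold,
    shift_range_days = config$shift_range_days,
    offset_summary = list(min = min(offsets), max = max(offsets),
                          mean = mean(offsets))
  )
  list(cohort = canonicalize_cohort(cohort(p, s)), audit = audit)
}
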