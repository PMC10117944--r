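# Candidate-site filters: cross-sample recurrence exclusion, allele-fraction
# floor, and zygosity calling with cross-sample purity checks.

#' Filtering configuration
#'
#' Defaults follow the published filtering rules: candidate sites with
#' AF <= 25% are excluded; 25% < AF < 80% is heterozygous and AF >= 80%
#' homozygous, both requiring AF < 5% in all other samples; sites shared by
#' two or more independent samples are treated as false positives (true
#' induced mutations cannot recur across independent M2 lines). The literal
#' "more than two samples" reading is available through
#' `recurrence_min_samples_to_exclude = 3`.
#'
#' @param af_floor exclude sites with AF at or below this fraction.
#' @param hom_min_af minimum AF for a homozygous call.
#' @param other_sample_max_af purity bound: all other samples must show AF
#'   strictly below this fraction.
#' @param recurrence_min_samples_to_exclude a site present in at least this
#'   many samples is removed from all of them.
#' @param sv_endpoint_tolerance bp tolerance when matching SV endpoints
#'   across samples/callers.
#' @return a `filter_config` list.
#' @export
filter_config <- function(af_floor = 0.25, hom_min_af = 0.80,
                          other_sample_max_af = 0.05,
                          recurrence_min_samples_to_exclude = 2L,
                          sv_endpoint_tolerance = 10L) {
  stopifnot(af_floor > 0, af_floor < hom_min_af, hom_min_af <= 1,
            other_sample_max_af >= 0, other_sample_max_af < af_floor,
            recurrence_min_samples_to_exclude >= 2)
  structure(list(af_floor = af_floor, hom_min_af = hom_min_af,
                 other_sample_max_af = other_sample_max_af,
                 recurrence_min_samples_to_exclude =
                   as.integer(recurrence_min_samples_to_exclude),
                 sv_endpoint_tolerance = as.integer(sv_endpoint_tolerance)),
            class = "filter_config")
}

# Assign a site key to every record. Explicit-allele records match exactly on
# (chrom, pos, ref, alt); SV-ish records (symbolic, BND) match on
# (chrom, sv class) with endpoint clustering within the configured tolerance.
site_keys <- function(records, tolerance = 10L) {
  n <- nrow(records)
  keys <- character(n)
  symbolic <- !is.na(records$alt) & grepl("^<", records$alt)
  bnd <- !is.na(records$sv_type) & records$sv_type == "BND"
  svish <- symbolic | bnd
  keys[!svish] <- paste(records$chrom[!svish], records$pos[!svish],
                        records$ref[!svish], records$alt[!svish], sep = ":")
  if (any(svish)) {
    idx <- which(svish)
    cls <- ifelse(bnd[idx], "BND",
                  sub("^<([A-Z]+)>$", "\\1", records$alt[idx]))
    grp <- paste(records$chrom[idx], cls, sep = ":")
    for (g in unique(grp)) {
      gi <- idx[grp == g]
      o <- gi[order(records$pos[gi])]
      cluster <- cumsum(c(1L, diff(records$pos[o]) > tolerance))
      # refine: require the end coordinate to agree within tolerance too
      ekey <- ifelse(is.na(records$end_pos[o]), 0L,
                     records$end_pos[o] %/% max(1L, tolerance))
      keys[o] <- paste("sv", g, cluster, ekey, sep = ":")
    }
  }
  keys
}

#' Remove candidate sites recurring across independent samples
#'
#' A site observed in `recurrence_min_samples_to_exclude` or more distinct
#' samples is removed from all of them and logged as a recurrent false
#' positive. SV endpoints match within `sv_endpoint_tolerance` bp.
#'
#' @param records a combined `variant_records` table covering all samples.
#' @param config a [filter_config()].
#' @return a list with `retained` (records), `excluded` (records) and `log`
#'   (data frame: site key, samples involved, n_samples).
#' @export
filter_recurrent <- function(records, config = filter_config()) {
  if (nrow(records) == 0)
    return(list(retained = records, excluded = records,
                log = data.frame(site = character(), samples = character(),
                                 n_samples = integer())))
  keys <- site_keys(records, config$sv_endpoint_tolerance)
  nsamp <- vapply(split(records$sample_id, keys),
                  function(s) length(unique(s)), integer(1))
  bad_keys <- names(nsamp)[nsamp >= config$recurrence_min_samples_to_exclude]
  drop <- keys %in% bad_keys
  log <- data.frame(
    site = bad_keys,
    samples = vapply(bad_keys, function(k)
      paste(sort(unique(records$sample_id[keys == k])), collapse = ","),
      character(1)),
    n_samples = as.integer(nsamp[bad_keys]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(retained = records[!drop, , drop = FALSE],
       excluded = records[drop, , drop = FALSE],
       log = log)
}

#' Call zygosity for one site
#'
#' Boundary handling follows the published rules exactly: AF = 25% is
#' excluded (the floor is inclusive), AF = 80% is homozygous, and an
#' other-sample AF of exactly 5% fails the strict `< 5%` purity check.
#'
#' @param af allele fraction of the candidate site in its sample.
#' @param other_sample_afs allele fractions of the same site in all other
#'   samples (zeros for samples without a record).
#' @param config a [filter_config()].
#' @return a list with `status` (`"homozygous"`, `"heterozygous"`,
#'   `"excluded"`) and `reason` (`"passed"`, `"af_at_or_below_floor"`,
#'   `"other_sample_contamination"`).
#' @export
call_zygosity <- function(af, other_sample_afs = numeric(0),
                          config = filter_config()) {
  if (is.na(af) || af < 0 || af > 1) stop("AF must lie in [0, 1], got ", af)
  if (length(other_sample_afs) > 0 &&
      (any(is.na(other_sample_afs)) || any(other_sample_afs < 0) ||
       any(other_sample_afs > 1)))
    stop("other-sample AFs must lie in [0, 1]")
  if (af <= config$af_floor)
    return(list(status = "excluded", reason = "af_at_or_below_floor"))
  pure <- length(other_sample_afs) == 0 ||
    max(other_sample_afs) < config$other_sample_max_af
  if (!pure)
    return(list(status = "excluded", reason = "other_sample_contamination"))
  if (af >= config$hom_min_af)
    return(list(status = "homozygous", reason = "passed"))
  list(status = "heterozygous", reason = "passed")
}

#' Apply all site filters to a multi-sample record table
#'
#' Runs the recurrence filter, then per record computes the other-sample
#' allele fractions at the matching site (0 when absent) and calls zygosity.
#' Records without an AF (no AD/DP in the source VCF) are excluded and
#' logged.
#'
#' @param records combined `variant_records` across samples and callers.
#' @param config a [filter_config()].
#' @return a list: `retained` records with added `zygosity` column
#'   (`"hom"`/`"het"`), `recurrence_log`, and `exclusions` (records with a
#'   `reason` column).
#' @export
apply_site_filters <- function(records, config = filter_config()) {
  rec <- filter_recurrent(records, config)
  r <- rec$retained
  if (nrow(r) == 0) {
    r$zygosity <- character(0)
    excl <- rec$excluded
    if (nrow(excl) > 0) excl$reason <- "recurrent_across_samples"
    else excl$reason <- character(0)
    return(list(retained = r, recurrence_log = rec$log, exclusions = excl))
  }
  keys <- site_keys(r, config$sv_endpoint_tolerance)
  status <- character(nrow(r))
  reason <- character(nrow(r))
  for (i in seq_len(nrow(r))) {
    if (is.na(r$af[i])) {
      status[i] <- "excluded"; reason[i] <- "missing_af"
      next
    }
    same_site <- keys == keys[i] & r$sample_id != r$sample_id[i]
    others <- r$af[same_site]
    others <- others[!is.na(others)]
    z <- call_zygosity(r$af[i], others, config)
    status[i] <- z$status; reason[i] <- z$reason
  }
  keep <- status %in% c("homozygous", "heterozygous")
  retained <- r[keep, , drop = FALSE]
  retained$zygosity <- ifelse(status[keep] == "homozygous", "hom", "het")
  dropped <- r[!keep, , drop = FALSE]
  if (nrow(dropped) > 0) dropped$reason <- reason[!keep]
  else dropped$reason <- character(0)
  excl_rec <- rec$excluded
  if (nrow(excl_rec) > 0) excl_rec$reason <- "recurrent_across_samples"
  else excl_rec$reason <- character(0)
  list(retained = retained, recurrence_log = rec$log,
       exclusions = rbind(excl_rec, dropped))
}
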