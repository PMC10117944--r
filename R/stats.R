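# Summary statistics over classified catalogs: mutation frequency, SBS
# spectra, rearrangement summaries, zygosity ratio, augmentation accounting,
# and group comparisons with compact letter displays.

#' Per-bp mutation frequency
#'
#' @param n_events number of mutation events.
#' @param genome_length reference length in bp.
#' @return events per bp.
#' @export
mutation_frequency <- function(n_events, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  n_events / genome_length
}

# The six merged-complement SBS classes, keyed by the pyrimidine-context
# original base pair. Transitions: G:C->A:T and A:T->G:C.
SBS_CLASSES <- c("GC_AT", "AT_GC", "GC_TA", "GC_CG", "AT_TA", "AT_CG")

# Map one ref/alt base substitution to its merged-complement class.
sbs_class_of <- function(ref, alt) {
  key <- paste0(toupper(ref), toupper(alt))
  map <- c(GA = "GC_AT", CT = "GC_AT",   # G:C -> A:T
           AG = "AT_GC", TC = "AT_GC",   # A:T -> G:C
           GT = "GC_TA", CA = "GC_TA",   # G:C -> T:A
           GC = "GC_CG", CG = "GC_CG",   # G:C -> C:G
           AT = "AT_TA", TA = "AT_TA",   # A:T -> T:A
           AC = "AT_CG", TG = "AT_CG")   # A:T -> C:G
  cls <- map[key]
  if (any(is.na(cls))) stop("not a substitution: ",
                            paste(key[is.na(cls)], collapse = ", "))
  unname(cls)
}

#' Merged-complement SBS spectrum with Ti/Tv and G:C/A:T ratios
#'
#' Complementary substitutions are merged (G>A with C>T, etc.) into six
#' classes. `ti_tv` is transitions (G:C->A:T, A:T->G:C) over the four
#' transversion classes. `gc_at` is the ratio of substitutions whose
#' original pair is G:C to those at A:T pairs; it is tested against the
#' genome's base composition with an exact binomial test (null probability
#' of a G:C original = genome GC content).
#'
#' @param ref,alt character vectors of original and substituted bases.
#' @param genome a `genome` object, or a GC fraction in (0, 1).
#' @return a `spectrum_summary` list: `counts` (named 6-vector), `ti_tv`,
#'   `gc_at`, `gc_at_p`, `n`.
#' @export
sbs_spectrum <- function(ref, alt, genome) {
  gc <- if (inherits(genome, "genome")) genome$gc_content else genome
  stopifnot(gc > 0, gc < 1, length(ref) == length(alt))
  cls <- if (length(ref)) sbs_class_of(ref, alt) else character(0)
  counts <- setNames(integer(length(SBS_CLASSES)), SBS_CLASSES)
  tab <- table(factor(cls, levels = SBS_CLASSES))
  counts[names(tab)] <- as.integer(tab)
  ti <- sum(counts[c("GC_AT", "AT_GC")])
  tv <- sum(counts[c("GC_TA", "GC_CG", "AT_TA", "AT_CG")])
  gc_orig <- sum(counts[c("GC_AT", "GC_TA", "GC_CG")])
  at_orig <- sum(counts[c("AT_GC", "AT_TA", "AT_CG")])
  n <- ti + tv
  res <- list(
    counts = counts,
    ti_tv = if (tv == 0) NA_real_ else ti / tv,
    gc_at = if (at_orig == 0) NA_real_ else gc_orig / at_orig,
    gc_at_p = if (n == 0) NA_real_ else
      binom.test(gc_orig, n, p = gc)$p.value,
    n = n)
  class(res) <- "spectrum_summary"
  res
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("<spectrum_summary>", x$n, "SBS\n")
  print(x$counts)
  cat(sprintf("Ti/Tv = %s   G:C/A:T = %s (p vs genome composition = %s)\n",
              format(round(x$ti_tv, 2)), format(round(x$gc_at, 2)),
              format(signif(x$gc_at_p, 3))))
  invisible(x)
}

#' Per-plant rearrangement summary
#'
#' @param catalog a classified `mutation_catalog`.
#' @param plants character vector of all plant (sample) ids in the group,
#'   including plants without any event.
#' @return list: `percent_plants_with_rearrangement` (whole percent),
#'   `mean_events_per_plant` (one decimal), plus raw `n_plants`,
#'   `n_plants_with`, `n_events`.
#' @export
rearrangement_summary <- function(catalog, plants = unique(catalog$sample)) {
  if (length(plants) == 0) stop("at least one plant is required")
  re <- group_rearrangements(catalog)
  with_re <- sum(plants %in% re$sample)
  n_events <- sum(re$sample %in% plants)
  list(percent_plants_with_rearrangement = round(100 * with_re /
                                                   length(plants)),
       mean_events_per_plant = round(n_events / length(plants), 1),
       n_plants = length(plants), n_plants_with = with_re,
       n_events = n_events)
}

#' Heterozygous:homozygous ratio with exact test against the M2 expectation
#'
#' Among M2 carriers of an induced mutation the expected homozygous fraction
#' is 1/3 (hom:het of 1:2). The observed homozygous count is tested against
#' that fraction with an exact binomial test.
#'
#' @param n_hom,n_het homozygous and heterozygous event counts.
#' @return list: `ratio_het_per_hom` (one decimal; `NA` when `n_hom` is 0),
#'   `p_vs_expected`.
#' @export
zygosity_ratio_test <- function(n_hom, n_het) {
  if (n_hom + n_het == 0) stop("no events")
  list(ratio_het_per_hom = if (n_hom == 0) NA_real_ else
    round(n_het / n_hom, 1),
    p_vs_expected = binom.test(n_hom, n_hom + n_het, p = 1 / 3)$p.value)
}

#' Multi-caller augmentation accounting
#'
#' @param n_base events detected by the base caller set.
#' @param n_added events newly added by the extra callers.
#' @param sv_before,sv_after SV event counts before/after augmentation.
#' @return list: `n_added`, `percent_of_total` (whole percent of the
#'   augmented total), `sv_before`, `sv_after`, `sv_fold` (one decimal;
#'   `NA` when `sv_before` is 0 with `sv_after` > 0).
#' @export
augmentation_report <- function(n_base, n_added, sv_before, sv_after) {
  stopifnot(n_base >= 0, n_added >= 0, sv_before >= 0, sv_after >= sv_before)
  total <- n_base + n_added
  fold <- if (sv_before == 0) {
    if (sv_after > 0) NA_real_ else 1.0
  } else round(sv_after / sv_before, 1)
  list(n_added = n_added,
       percent_of_total = round(100 * n_added / total),
       sv_before = sv_before, sv_after = sv_after, sv_fold = fold)
}

# ---- compact letter displays ----------------------------------------------

# Insert-absorb compact letter display. `signif_pairs` is a 2-column matrix
# of group-name pairs declared significantly different. Groups sharing no
# letter differ; groups sharing any letter do not.
compact_letters <- function(groups, signif_pairs) {
  sets <- list(groups)
  if (!is.null(signif_pairs) && nrow(signif_pairs) > 0) {
    for (k in seq_len(nrow(signif_pairs))) {
      a <- signif_pairs[k, 1]; b <- signif_pairs[k, 2]
      hit <- vapply(sets, function(s) a %in% s && b %in% s, logical(1))
      children <- list()
      for (i in which(hit)) {
        children <- c(children, list(setdiff(sets[[i]], a)),
                      list(setdiff(sets[[i]], b)))
      }
      sets <- c(sets[!hit], children)
      sets <- sets[vapply(sets, length, integer(1)) > 0]
      # absorb sets wholly contained in another
      keep <- rep(TRUE, length(sets))
      for (i in seq_along(sets)) for (j in seq_along(sets)) {
        if (i != j && keep[i] && keep[j] &&
            all(sets[[i]] %in% sets[[j]]) &&
            (length(sets[[i]]) < length(sets[[j]]) || i > j))
          keep[i] <- FALSE
      }
      sets <- sets[keep]
    }
  }
  # stable letter order: by first group appearance
  ord <- order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))
  sets <- sets[ord]
  letters_used <- letters[seq_along(sets)]
  vapply(groups, function(g)
    paste(letters_used[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = ""), character(1))
}

#' Pairwise Fisher tests on category proportions with compact letters
#'
#' For each pair of groups, a 2x2 Fisher exact test of
#' category-of-interest vs. the rest; p-values are adjusted (Holm by
#' default) and a compact letter display is derived at `alpha`.
#'
#' @param counts_of_interest named integer vector: events in the category of
#'   interest per group.
#' @param totals named integer vector: total events per group.
#' @param alpha significance level.
#' @param method p-adjustment method (`"holm"`, `"bonferroni"`, `"BH"`).
#' @return a `group_comparison` list: `groups`, `statistic` (proportions),
#'   `pairs` (data frame with raw and adjusted p), `letters`.
#' @export
proportion_test <- function(counts_of_interest, totals, alpha = 0.05,
                            method = c("holm", "bonferroni", "BH")) {
  method <- match.arg(method)
  stopifnot(length(counts_of_interest) == length(totals),
            !is.null(names(totals)))
  zero <- totals == 0
  if (any(zero)) {
    warning("excluding group(s) with zero total events: ",
            paste(names(totals)[zero], collapse = ", "))
    counts_of_interest <- counts_of_interest[!zero]
    totals <- totals[!zero]
  }
  groups <- names(totals)
  if (length(groups) < 2) stop("at least two groups with events are required")
  cmb <- utils::combn(groups, 2)
  p <- apply(cmb, 2, function(pr) {
    m <- matrix(c(counts_of_interest[pr[1]],
                  totals[pr[1]] - counts_of_interest[pr[1]],
                  counts_of_interest[pr[2]],
                  totals[pr[2]] - counts_of_interest[pr[2]]),
                nrow = 2, byrow = TRUE)
    fisher.test(m)$p.value
  })
  padj <- p.adjust(p, method)
  pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ], p = p,
                      p_adj = padj, stringsAsFactors = FALSE)
  sig <- as.matrix(pairs[pairs$p_adj < alpha, c("group1", "group2")])
  res <- list(groups = groups,
              statistic = setNames(counts_of_interest / totals, groups),
              pairs = pairs,
              letters = compact_letters(groups, sig),
              alpha = alpha, method = method)
  class(res) <- "group_comparison"
  res
}

#' One-way ANOVA with Tukey HSD post hoc and compact letters
#'
#' @param values numeric vector of per-sample values.
#' @param group factor/character vector of group labels, same length.
#' @param alpha significance level.
#' @return a `group_comparison` list: `groups`, `statistic` (group means),
#'   `anova_f`, `anova_p`, `pairs` (Tukey-adjusted), `letters`,
#'   `degenerate` flag (TRUE when the within-group variance is zero).
#' @export
anova_with_cld <- function(values, group, alpha = 0.05) {
  group <- as.character(group)
  stopifnot(length(values) == length(group))
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with fewer than 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    values <- values[keep]; group <- group[keep]
  }
  groups <- unique(group)
  if (length(groups) < 2) stop("at least two groups are required")
  means <- vapply(split(values, group), mean, numeric(1))[groups]
  if (var(values) == 0) {
    res <- list(groups = groups, statistic = means, anova_f = NA_real_,
                anova_p = NA_real_,
                pairs = data.frame(group1 = character(),
                                   group2 = character(), p_adj = numeric()),
                letters = compact_letters(groups, NULL),
                alpha = alpha, degenerate = TRUE)
    class(res) <- "group_comparison"
    return(res)
  }
  d <- data.frame(y = values, g = factor(group, levels = groups))
  fit <- aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  prs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairs <- data.frame(group1 = prs[, 2], group2 = prs[, 1],
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE, row.names = NULL)
  sig <- as.matrix(pairs[pairs$p_adj < alpha, c("group1", "group2")])
  res <- list(groups = groups, statistic = means,
              anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
              pairs = pairs, letters = compact_letters(groups, sig),
              alpha = alpha, degenerate = FALSE)
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(data.frame(group = x$groups,
                   statistic = round(unname(x$statistic[x$groups]), 3),
                   letters = unname(x$letters[x$groups])))
  invisible(x)
}
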