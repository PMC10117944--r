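test_that("mutation_frequency is events per reference bp", {
  expect_equal(mutation_frequency(0, 1.19e8), 0)
  expect_equal(mutation_frequency(119, 1.19e8), 1e-6)
  expect_error(mutation_frequency(1, 0), "positive")
})

test_that("sbs_spectrum merges complements and derives Ti/Tv and G:C/A:T", {
  s <- sbs_spectrum(c("G", "C", "A", "T"), c("A", "T", "C", "G"), 0.36)
  expect_equal(s$ti_tv, 1.0)        # 2 transitions, 2 transversions
  expect_equal(s$gc_at, 1.0)        # 2 G:C originals, 2 A:T originals
  expect_equal(sum(s$counts), 4L)
  # complement-strand relabeling leaves the class counts unchanged
  comp <- c(G = "C", C = "G", A = "T", T = "A")
  s2 <- sbs_spectrum(comp[c("G", "C", "A", "T")], comp[c("A", "T", "C", "G")],
                     0.36)
  expect_equal(s2$counts, s$counts)
  # no transversions: Ti/Tv flagged undefined, not infinite
  s3 <- sbs_spectrum(c("G", "A"), c("A", "G"), 0.36)
  expect_true(is.na(s3$ti_tv))
  expect_error(sbs_spectrum("G", "G", 0.36), "not a substitution")
})

test_that("gc_at matches the genome-composition constant under the null", {
  # substitutions placed uniformly on a GC=0.36 genome: expected
  # G:C/A:T original ratio is 0.36/0.64 = 0.5625 (prints as 0.56)
  expect_equal(round(0.36 / 0.64, 2), 0.56)
  g <- small_genome(seed = 71, length = 2e5, n_chrom = 1)
  set.seed(72)
  n <- 10000
  pos <- sample.int(g$total_length, n)
  ref <- strsplit(as.character(g$sequences[[1]]), "")[[1]][pos]
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  s <- sbs_spectrum(ref, alt, g)
  p0 <- g$gc_content
  # observed ratio within 3 binomial sigma of the composition ratio
  se <- 3 * sqrt(p0 * (1 - p0) / n)
  gc_frac <- s$gc_at / (1 + s$gc_at)
  expect_lt(abs(gc_frac - p0), se)
  expect_gt(s$gc_at_p, 0.001)
})

test_that("rearrangement_summary reproduces percent and mean bookkeeping", {
  plants <- sprintf("p%02d", 1:12)
  ev <- do.call(rbind, lapply(1:19, function(i)
    mutation_event(plants[(i %% 10) + 1], "chr1", i * 1000, i * 1000 + 200,
                   "DelGE100", -201, "het")))
  rs <- rearrangement_summary(ev, plants)
  expect_equal(rs$percent_plants_with_rearrangement, 83)  # 10/12
  expect_equal(rs$mean_events_per_plant, 1.6)             # 19/12
  empty <- rearrangement_summary(ev[0, ], plants)
  expect_equal(empty$percent_plants_with_rearrangement, 0)
  expect_equal(empty$mean_events_per_plant, 0)
  expect_error(rearrangement_summary(ev, character(0)), "plant")
})

test_that("zygosity_ratio_test matches the exact binomial oracle", {
  z <- zygosity_ratio_test(16, 34)
  expect_equal(z$ratio_het_per_hom, 2.1)
  expect_equal(zygosity_ratio_test(12, 18)$ratio_het_per_hom, 1.5)
  # (10, 20) is the most probable outcome under hom fraction 1/3:
  # oracle = sum of binomial masses not exceeding P(X = 10)
  p10 <- dbinom(10, 30, 1/3)
  oracle <- sum(dbinom(0:30, 30, 1/3)[dbinom(0:30, 30, 1/3) <= p10 * (1 + 1e-7)])
  expect_equal(zygosity_ratio_test(10, 20)$p_vs_expected, oracle,
               tolerance = 1e-6)
  expect_true(is.na(zygosity_ratio_test(0, 5)$ratio_het_per_hom))
  expect_error(zygosity_ratio_test(0, 0), "no events")
})

test_that("augmentation_report reproduces the accounting identities", {
  a <- augmentation_report(2531, 25, 30, 50)
  expect_equal(a$percent_of_total, 1)      # 25 / 2556
  expect_equal(a$sv_fold, 1.7)             # 50 / 30
  b <- augmentation_report(100, 0, 10, 10)
  expect_equal(b$percent_of_total, 0)
  expect_equal(b$sv_fold, 1.0)
  expect_true(is.na(augmentation_report(10, 5, 0, 3)$sv_fold))
})

test_that("proportion_test flags real differences and not identical groups", {
  # identical composition: all adjusted p = 1, one shared letter
  r <- proportion_test(c(a = 20, b = 20, c = 20), c(a = 100, b = 100, c = 100))
  expect_true(all(r$pairs$p_adj == 1))
  expect_equal(unname(r$letters), rep("a", 3))
  # 50/100 vs 5/100: oracle p from the hypergeometric distribution directly
  r2 <- proportion_test(c(g1 = 50, g2 = 5), c(g1 = 100, g2 = 100))
  k <- 0:55
  dens <- dhyper(k, 100, 100, 55)
  oracle <- sum(dens[dens <= dhyper(50, 100, 100, 55) * (1 + 1e-7)])
  expect_equal(r2$pairs$p, oracle, tolerance = 1e-9)
  expect_lt(r2$pairs$p_adj, 0.05)
  expect_false(r2$letters[["g1"]] == r2$letters[["g2"]])
  # three groups, only one extreme pair differs -> two letters, shared middle
  r3 <- proportion_test(c(x = 50, y = 30, z = 10), c(x = 100, y = 100, z = 100))
  sig <- r3$pairs$p_adj < 0.05
  # letter display consistency: significant pairs share no letter,
  # non-significant pairs share at least one
  for (i in seq_len(nrow(r3$pairs))) {
    l1 <- strsplit(r3$letters[[r3$pairs$group1[i]]], "")[[1]]
    l2 <- strsplit(r3$letters[[r3$pairs$group2[i]]], "")[[1]]
    if (sig[i]) expect_length(intersect(l1, l2), 0)
    else expect_gt(length(intersect(l1, l2)), 0)
  }
  # zero-total groups are excluded with a warning
  expect_warning(proportion_test(c(a = 5, b = 0, c = 6),
                                 c(a = 10, b = 0, c = 10)), "zero total")
})

test_that("Holm never declares more significant pairs than unadjusted Fisher", {
  set.seed(81)
  for (i in 1:25) {
    k <- sample(3:5, 1)
    tot <- sample(40:120, k, replace = TRUE)
    ct <- rbinom(k, tot, runif(1, 0.1, 0.6))
    names(tot) <- names(ct) <- paste0("g", seq_len(k))
    r <- proportion_test(ct, tot)
    expect_lte(sum(r$pairs$p_adj < 0.05), sum(r$pairs$p < 0.05))
    expect_true(all(r$pairs$p_adj >= r$pairs$p))
  }
})

test_that("anova_with_cld separates distant means and not null groups", {
  set.seed(91)
  # two groups 10 sigma apart get distinct letters
  v <- c(rnorm(6, 0, 1), rnorm(6, 10, 1))
  g <- rep(c("a", "b"), each = 6)
  r <- anova_with_cld(v, g)
  expect_lt(r$anova_p, 0.001)
  expect_false(r$letters[["a"]] == r$letters[["b"]])
  # identical constants: degenerate flag, shared letter
  r2 <- anova_with_cld(rep(5, 12), rep(c("a", "b", "c"), each = 4))
  expect_true(r2$degenerate)
  expect_equal(unname(r2$letters), rep("a", 3))
  # single-sample groups are excluded with warning
  expect_warning(anova_with_cld(c(1, 2, 3, 4, 9), rep(c("a", "b", "c"),
                                                      c(2, 2, 1))),
                 "fewer than 2")
})

test_that("one-way ANOVA keeps its nominal type-I rate on null groups", {
  set.seed(93)
  rej <- replicate(400, {
    v <- rnorm(18)
    anova_with_cld(v, rep(c("a", "b", "c"), each = 6))$anova_p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("compact letters match a brute-force consistency check", {
  set.seed(95)
  for (i in 1:50) {
    k <- sample(3:6, 1)
    groups <- paste0("g", seq_len(k))
    pairs <- t(combn(groups, 2))
    sig <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    lt <- radmut:::compact_letters(groups, sig)
    sigset <- paste(sig[, 1], sig[, 2])
    for (r in seq_len(nrow(pairs))) {
      shared <- length(intersect(strsplit(lt[[pairs[r, 1]]], "")[[1]],
                                 strsplit(lt[[pairs[r, 2]]], "")[[1]]))
      if (paste(pairs[r, 1], pairs[r, 2]) %in% sigset)
        expect_equal(shared, 0)
      else expect_gt(shared, 0)
    }
  }
})
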