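test_that("net_indel_length scores deletions with unknown-sequence insertions", {
  expect_equal(net_indel_length(10, 3), -7L)   # 10-del + 3-ins = 7-base deletion
  expect_equal(net_indel_length(1, 0), -1L)
  expect_equal(net_indel_length(0, 150), 150L)
  expect_error(net_indel_length(0, 0), "not an InDel")
})

test_that("categorize maps net lengths onto the eight-category scheme", {
  expect_equal(categorize("indel", -150), "DelGE100")
  expect_equal(categorize("indel", -7), "Del2_99")
  expect_equal(categorize("indel", 5), "Ins2_99")
  expect_equal(categorize("indel", 1), "Ins1")
  expect_equal(categorize("indel", -1), "Del1")
  expect_equal(categorize("substitution"), "SBS")
  expect_equal(categorize("inversion"), "SV")
  expect_equal(categorize("translocation"), "SV")
  # insertions >= 100 bp have no category and must error explicitly
  expect_error(categorize("indel", 150), "no category")
})

test_that("allele decomposition splits substitution blocks on reference runs", {
  # REF=ACGTA ALT=TCGTC: matches at offsets 1-3 -> two SBS primitives
  d <- radmut:::decompose_alleles("chr1", 100L, "ACGTA", "TCGTC")
  expect_equal(d$type, c("SBS", "SBS"))
  expect_equal(d$start, c(100L, 104L))
  # anchored deletion
  d2 <- radmut:::decompose_alleles("chr1", 99L, "ATTG", "A")
  expect_equal(d2$type, "Del")
  expect_equal(d2$start, 100L)
  expect_equal(d2$end, 102L)
  expect_equal(d2$net, -3L)
  # anchored insertion
  d3 <- radmut:::decompose_alleles("chr1", 50L, "G", "GTTA")
  expect_equal(d3$type, "Ins")
  expect_equal(d3$start, 50L)
  expect_equal(d3$net, 3L)
  # mixed-length block: 5 deleted, 2 inserted -> net -3 deletion
  d4 <- radmut:::decompose_alleles("chr1", 10L, "AACGTG", "ATT")
  expect_equal(d4$net, -3L)
})

test_that("merge_complex follows the gap rule on the worked examples", {
  cfg <- classify_config()
  p2 <- data.frame(type = c("SBS", "SBS"), chrom = "chr1",
                   start = c(100L, 105L), end = c(100L, 105L), net = 0L)
  ev <- merge_complex(p2, cfg)                   # gap 4 < 10 -> one Complex
  expect_equal(ev$category, "Complex")
  expect_equal(nrow(radmut:::parse_components(ev$components)), 2)
  p3 <- data.frame(type = c("SBS", "SBS"), chrom = "chr1",
                   start = c(100L, 120L), end = c(100L, 120L), net = 0L)
  ev3 <- merge_complex(p3, cfg)                  # gap 19 >= 10 -> two SBS
  expect_equal(ev3$category, c("SBS", "SBS"))
  # large indels terminate clusters
  p4 <- data.frame(type = c("SBS", "Del"), chrom = "chr1",
                   start = c(100L, 104L), end = c(100L, 153L),
                   net = c(0L, -50L))
  ev4 <- merge_complex(p4, cfg)
  expect_setequal(ev4$category, c("SBS", "Del2_99"))
  # min_cluster_size = 3 gives the literal "more than two" reading
  ev5 <- merge_complex(p2, classify_config(min_cluster_size = 3))
  expect_equal(ev5$category, c("SBS", "SBS"))
  expect_error(merge_complex(p2[2:1, ], cfg), "sorted")
})

test_that("merge_complex agrees with the pairwise union-find oracle", {
  cfg <- classify_config()
  set.seed(53)
  for (i in 1:200) {
    prim <- random_layout()
    ev <- merge_complex(prim, cfg)
    cl <- oracle_clusters(prim)
    sizes <- table(cl)
    eligible <- prim$type == "SBS" | abs(prim$net) <= 9
    n_complex_oracle <- sum(sizes >= 2)
    # oracle clusters of size >= 2 are complex iff all members eligible
    expect_equal(sum(ev$category == "Complex"), n_complex_oracle,
                 info = paste("layout", i))
    expect_equal(nrow(ev), length(sizes), info = paste("layout", i))
    # idempotence: re-merging the simple events changes nothing
    simple <- ev[ev$category != "Complex", , drop = FALSE]
    if (nrow(simple) > 0) {
      prim2 <- data.frame(
        type = ifelse(simple$category == "SBS", "SBS",
                      ifelse(simple$net_length > 0, "Ins", "Del")),
        chrom = simple$chrom, start = simple$start, end = simple$end,
        net = simple$net_length)
      # only those isolated by >= gap_threshold remain simple, so the
      # re-merge must reproduce them exactly
      ev2 <- merge_complex(prim2, cfg)
      expect_equal(ev2$category, simple$category)
    }
  }
})

test_that("complexity_subclass counts indel components", {
  mk <- function(comp) mutation_event("p", "chr1", 1, 50, "Complex", 0, "het",
                                      components = comp)
  expect_equal(complexity_subclass(mk("SBS@1:+0;SBS@5:+0")), "no_indel")
  expect_equal(complexity_subclass(mk("SBS@1:+0;Del@5:-3")), "one_indel")
  expect_equal(complexity_subclass(mk("Del@1:-1;Ins@5:+1;SBS@9:+0")),
               "two_plus_indels")
  expect_error(complexity_subclass(
    mutation_event("p", "chr1", 1, 1, "SBS", 0, "het")), "Complex")
})

test_that("group_rearrangements selects exactly SV and DelGE100", {
  cat <- rbind(
    mutation_event("p1", "chr1", 1, 1, "SBS", 0, "het"),
    mutation_event("p1", "chr1", 10, 10, "Del1", -1, "het"),
    mutation_event("p1", "chr1", 100, 300, "DelGE100", -201, "hom"),
    mutation_event("p1", "chr2", 5, 800, "SV", 0, "het",
                   sv_kind = "inversion"))
  re <- group_rearrangements(cat)
  expect_setequal(re$category, c("DelGE100", "SV"))
  expect_equal(nrow(group_rearrangements(cat[1:2, ])), 0)
  # simulated catalog: rearrangement count matches truth
  tr <- simulate_catalog(default_profiles()$carbon_dry, 4, small_genome(),
                        seed = 57)
  k <- sum(tr$events$category %in% c("SV", "DelGE100"))
  expect_equal(nrow(group_rearrangements(truth_catalog(tr))), k)
})

test_that("classification recovery on noise-free records is exact", {
  g <- small_genome(seed = 61)
  tr <- simulate_catalog(default_profiles()$carbon_seedling, 3, g, seed = 62)
  em <- emit_caller_outputs(tr, tempfile("cls"), seed = 63)
  h <- harmonize_vcfs(em$manifest)
  truth <- truth_catalog(tr)
  # category confusion matrix is diagonal
  key <- paste(truth$sample, truth$chrom, truth$start)
  ckey <- paste(h$catalog$sample, h$catalog$chrom, h$catalog$start)
  m <- match(key, ckey)
  expect_false(anyNA(m))
  expect_equal(h$catalog$category[m], truth$category)
  expect_equal(h$catalog$net_length[m], truth$net_length)
})
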