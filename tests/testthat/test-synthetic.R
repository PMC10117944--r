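test_that("make_genome is seed-reproducible and hits its GC target", {
  g1 <- make_genome(1e5, 0.36, seed = 7)
  g2 <- make_genome(1e5, 0.36, seed = 7)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  # 3-sigma binomial bound on the GC estimate at this length
  expect_lt(abs(g1$gc_content - 0.36), 3 * sqrt(0.36 * 0.64 / 1e5))
  expect_error(make_genome(5e3, 0.36), "10 kb")
  expect_error(make_genome(1e5, 1.2), "gc")
})

test_that("treatment profiles validate their probability vectors", {
  p <- default_profiles()
  expect_length(p, 4)
  for (pr in p) {
    expect_equal(sum(pr$category_mix), 1, tolerance = 1e-9)
    expect_equal(sum(pr$sbs_class_mix), 1, tolerance = 1e-9)
  }
  bad <- p$gamma_dry$category_mix
  bad["SBS"] <- bad["SBS"] + 0.01
  expect_error(treatment_profile("x", 10, bad, p$gamma_dry$sbs_class_mix),
               "sum to 1")
})

test_that("simulated catalogs follow the profile's stated world", {
  g <- small_genome(seed = 121, length = 2e5)
  prof <- default_profiles()$carbon_dry
  tr <- simulate_catalog(prof, 40, g, seed = 122)
  ev <- tr$events
  n <- nrow(ev)
  # category empirical mix within 4-sigma multinomial bounds
  for (cc in names(prof$category_mix)) {
    p <- prof$category_mix[[cc]]
    phat <- mean(ev$category == cc)
    expect_lt(abs(phat - p), 4 * sqrt(p * (1 - p) / n) + 2 / n)
  }
  # deletion size ranges respect their categories
  expect_true(all(ev$net_length[ev$category == "Del1"] == -1))
  expect_true(all(ev$net_length[ev$category == "Del2_99"] %in% -(2:99)))
  expect_true(all(ev$net_length[ev$category == "DelGE100"] <= -100))
  # complex events have >= 2 components with gaps < 10
  cx <- ev[ev$category == "Complex", ]
  for (i in seq_len(nrow(cx))) {
    comp <- radmut:::parse_components(cx$components[i])
    expect_gte(nrow(comp), 2)
  }
  # bit-reproducible under the seed
  tr2 <- simulate_catalog(prof, 40, g, seed = 122)
  expect_identical(tr$events, tr2$events)
})

test_that("emitted allele fractions track zygosity under read sampling", {
  g <- small_genome(seed = 131, length = 1e5)
  prof <- default_profiles()$gamma_seedling
  tr <- simulate_catalog(prof, 6, g, seed = 132)
  em <- emit_caller_outputs(tr, tempfile("af"),
                            noise = emission_noise(af_depth = TRUE,
                                                   depth = 40),
                            seed = 133)
  recs <- do.call(bind_records, lapply(seq_len(nrow(em$manifest)), function(i)
    read_caller_vcf(em$manifest$path[i], em$manifest$caller[i],
                    em$manifest$sample[i])))
  # het SBS records: AF distribution centered on 0.5
  truth_het <- tr$primitives[tr$primitives$zygosity == "het" &
                               tr$primitives$category == "SBS", ]
  m <- merge(recs, truth_het[, c("chrom", "pos", "alt")],
             by = c("chrom", "pos", "alt"))
  expect_gt(nrow(m), 30)
  expect_lt(abs(mean(m$af) - 0.5), 3 * sqrt(0.25 / (40 * nrow(m))) + 0.01)
  # stored AF equals alt reads / depth by construction
  expect_true(all(abs(recs$af - round(recs$af * recs$depth) / recs$depth)
                  < 1e-9))
})

test_that("per-caller sensitivity thins detections as specified", {
  g <- small_genome(seed = 141, length = 1e5)
  prof <- default_profiles()$carbon_dry
  tr <- simulate_catalog(prof, 10, g, seed = 142)
  em <- emit_caller_outputs(
    tr, tempfile("sens"),
    callers = c("snv_indel_caller", "combined_caller_a", "combined_caller_b"),
    noise = emission_noise(sensitivity = list(snv_indel_caller = 1,
                                              combined_caller_a = 1,
                                              combined_caller_b = 0.5)),
    seed = 143)
  counts <- vapply(split(em$manifest$path, em$manifest$caller), function(ps)
    sum(vapply(ps, function(p)
      nrow(read_caller_vcf(p, "sr_caller", "x")), integer(1))), integer(1))
  expect_lt(counts[["combined_caller_b"]], counts[["combined_caller_a"]])
  expect_gt(counts[["combined_caller_b"]], 0)
})

test_that("injected shared false positives are fully removed by the filter", {
  g <- small_genome(seed = 151, length = 1e5)
  prof <- default_profiles()$carbon_seedling
  tr <- simulate_catalog(prof, 6, g, seed = 152)
  em <- emit_caller_outputs(tr, tempfile("fp"),
                            noise = emission_noise(fp_shared_rate = 0.5),
                            seed = 153)
  expect_gt(nrow(em$fp_log), 0)
  h <- harmonize_vcfs(em$manifest)
  # every injected site appears in the recurrence log
  expect_gte(nrow(h$recurrence_log), nrow(em$fp_log))
  # precision 1 against truth proves no false positive survived;
  # recall 1 proves the filter removed nothing real
  r <- recovery_stats(h$catalog, tr)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)
})
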