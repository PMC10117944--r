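genes_fixture <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3", "te1"),
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    start = c(1000L, 3000L, 500L, 6000L),
    end = c(1900L, 3800L, 1500L, 6900L),
    strand = "+",
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "transposable_element"),
    stringsAsFactors = FALSE)
}

test_that("genes_affected reports overlapped protein-coding genes only", {
  genes <- genes_fixture()
  del <- mutation_event("p1", "chr1", 900, 4000, "DelGE100", -3101, "hom")
  expect_equal(genes_affected(del, genes), c("g1", "g2"))
  sbs <- mutation_event("p1", "chr1", 2500, 2500, "SBS", 0, "het")
  expect_equal(genes_affected(sbs, genes), character(0))
  # non-coding biotypes never count
  te_hit <- mutation_event("p1", "chr1", 6100, 6100, "SBS", 0, "het")
  expect_equal(genes_affected(te_hit, genes), character(0))
  expect_error(genes_affected(
    mutation_event("p1", "chrX", 5, 5, "SBS", 0, "het"), genes),
    "unknown chromosome")
})

test_that("translocations affect junction genes, not the span between", {
  genes <- genes_fixture()
  tr <- mutation_event("p1", "chr1", 1500, 1500, "SV", 0, "het",
                       sv_kind = "translocation",
                       components = "J@chr1:1500;J@chr2:800")
  expect_equal(genes_affected(tr, genes), c("g1", "g3"))
  # junctions in intergenic space affect nothing despite the wide "span"
  tr2 <- mutation_event("p1", "chr1", 2500, 2500, "SV", 0, "het",
                        sv_kind = "translocation",
                        components = "J@chr1:2500;J@chr2:5000")
  expect_equal(genes_affected(tr2, genes), character(0))
})

test_that("a 282 kb deletion over a packed block takes out all 60 genes", {
  g <- make_genome(6e5, 0.36, seed = 103, n_chrom = 1)
  genes <- make_gene_models(g, n_genes = 20, seed = 104,
                            packed_block = list(n = 60, span = 282000,
                                                chrom = "chr1",
                                                start = 150000))
  del <- mutation_event("p1", "chr1", 149000, 149000 + 282000, "DelGE100",
                        -282001, "hom")
  hit <- genes_affected(del, genes)
  expect_true(all(sprintf("packed_g%03d", 1:60) %in% hit))
  # brute-force overlap scan agrees with the indexed implementation
  brute <- genes$gene_id[genes$biotype == "protein_coding" &
                           genes$chrom == "chr1" &
                           genes$start <= del$end & genes$end >= del$start]
  expect_setequal(hit, brute)
})

test_that("indexed overlap equals brute force on random fixtures", {
  set.seed(105)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    gs <- sort(sample.int(50000, n))
    genes <- data.frame(gene_id = paste0("g", seq_len(n)), chrom = "chr1",
                        start = gs, end = gs + sample(50:400, n, TRUE),
                        strand = "+", biotype = "protein_coding",
                        stringsAsFactors = FALSE)
    s <- sample.int(50000, 1)
    ev <- mutation_event("p", "chr1", s, s + sample(0:5000, 1), "DelGE100",
                         -5000, "hom")
    brute <- sort(genes$gene_id[genes$start <= ev$end & genes$end >= ev$start])
    expect_equal(genes_affected(ev, genes), brute)
  }
})

test_that("per_plant_gene_counts honors the multi-gene exclusion", {
  genes <- genes_fixture()
  cat <- rbind(
    mutation_event("p1", "chr1", 1100, 1100, "SBS", 0, "hom"),        # g1
    mutation_event("p1", "chr1", 2900, 3900, "DelGE100", -1001, "hom"), # g2 (1 gene)
    mutation_event("p2", "chr1", 900, 4000, "DelGE100", -3101, "hom"),  # g1+g2
    mutation_event("p2", "chr2", 700, 700, "Del1", -1, "het"))          # g3
  all_counts <- per_plant_gene_counts(cat, genes, exclude_multigene = FALSE)
  expect_equal(all_counts, c(p1 = 2L, p2 = 3L))
  excl <- per_plant_gene_counts(cat, genes, exclude_multigene = TRUE)
  expect_equal(excl, c(p1 = 2L, p2 = 1L))
  # exclusion can only lower counts
  expect_true(all(excl <= all_counts))
  hom <- per_plant_gene_counts(cat, genes, zygosity_filter = "hom_only")
  expect_equal(hom[["p2"]], 2L)
  # unresolved SVs are dropped
  cat2 <- rbind(cat, mutation_event("p3", "chr1", 1200, 1200, "SV", 0, "het",
                                    sv_kind = "inversion",
                                    structure_resolved = FALSE))
  expect_equal(per_plant_gene_counts(cat2, genes,
                                     plants = "p3")[["p3"]], 0L)
  # empty plant
  expect_equal(per_plant_gene_counts(cat, genes,
                                     plants = "p9")[["p9"]], 0L)
})

test_that("GFF3 round trip preserves gene models", {
  g <- make_genome(3e5, 0.36, seed = 107, n_chrom = 2)
  genes <- make_gene_models(g, 25, seed = 108)
  path <- tempfile(fileext = ".gff3")
  write_gff3(genes, path)
  back <- read_gene_models(path)
  rownames(genes) <- NULL
  expect_equal(back, genes)
})
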