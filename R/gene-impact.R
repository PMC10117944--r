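# Per-plant counts of protein-coding genes affected by classified mutations,
# with the variant that excludes events spanning two or more genes.

#' Read gene models from a GFF3 subset
#'
#' Reads `gene`-type features from a GFF3 file (9 columns); the `ID` and
#' `biotype`/`gene_biotype` attributes are honored. Features without a
#' biotype attribute default to `protein_coding`.
#'
#' @param path GFF3 file.
#' @return data frame of gene models: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @export
read_gene_models <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), biotype = character(),
                      stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  if (ncol(f) != 9) stop("GFF3 lines must have 9 tab-separated columns")
  keep <- f[, 3] == "gene"
  f <- f[keep, , drop = FALSE]
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  ids <- attr_get(f[, 9], "ID")
  bio <- attr_get(f[, 9], "biotype")
  bio2 <- attr_get(f[, 9], "gene_biotype")
  bio[is.na(bio)] <- bio2[is.na(bio)]
  bio[is.na(bio)] <- "protein_coding"
  gm <- data.frame(gene_id = ids, chrom = f[, 1],
                   start = as.integer(f[, 4]), end = as.integer(f[, 5]),
                   strand = f[, 7], biotype = bio, stringsAsFactors = FALSE)
  if (anyNA(gm$gene_id)) stop("gene feature(s) without an ID attribute")
  if (anyDuplicated(gm$gene_id)) stop("gene ids must be unique")
  gm
}

gene_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         gene_id = genes$gene_id)
}

# Spans an event contributes for overlap counting. Point events span their
# interval; translocations and breakend-defined inversions contribute their
# junction points (+-1 bp), not the intervening sequence.
event_spans <- function(event) {
  if (event$category == "SV" && event$components != ".") {
    parts <- strsplit(event$components, ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^J@([^:]+):([0-9]+)$", parts))
    ok <- vapply(m, length, integer(1)) == 3
    if (all(ok)) {
      ch <- vapply(m, `[`, character(1), 2)
      ps <- as.integer(vapply(m, `[`, character(1), 3))
      return(data.frame(chrom = ch, start = pmax(1L, ps - 1L),
                        end = ps + 1L, stringsAsFactors = FALSE))
    }
  }
  data.frame(chrom = event$chrom, start = event$start, end = event$end,
             stringsAsFactors = FALSE)
}

#' Protein-coding genes overlapped by one mutation event
#'
#' @param event a one-row `mutation_catalog` entry.
#' @param genes gene models as from [read_gene_models()].
#' @return character vector of affected protein-coding gene ids.
#' @export
genes_affected <- function(event, genes) {
  stopifnot(is.data.frame(event), nrow(event) == 1)
  pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  if (nrow(pc) == 0) return(character(0))
  spans <- event_spans(event)
  if (!all(spans$chrom %in% c(pc$chrom, genes$chrom)))
    stop("event on unknown chromosome: ",
         paste(setdiff(spans$chrom, genes$chrom), collapse = ", "))
  gr <- gene_granges(pc)
  q <- GenomicRanges::GRanges(spans$chrom,
                              IRanges::IRanges(spans$start, spans$end))
  hits <- GenomicRanges::findOverlaps(q, gr)
  sort(unique(pc$gene_id[S4Vectors::subjectHits(hits)]))
}

#' Genes affected per plant
#'
#' Counts, for each plant, the protein-coding genes hit by qualifying
#' events. With `exclude_multigene = TRUE`, events whose affected-gene set
#' has two or more members are dropped before counting (the large-deletion
#' exclusion). SV events whose overall structure is unresolved are always
#' dropped.
#'
#' @param catalog a classified `mutation_catalog`.
#' @param genes gene models.
#' @param exclude_multigene drop events affecting >= 2 genes.
#' @param zygosity_filter `"all"` or `"hom_only"`.
#' @param plants plant ids to report (defaults to those present).
#' @return named integer vector of per-plant affected-gene counts.
#' @export
per_plant_gene_counts <- function(catalog, genes, exclude_multigene = FALSE,
                                  zygosity_filter = c("all", "hom_only"),
                                  plants = unique(catalog$sample)) {
  zygosity_filter <- match.arg(zygosity_filter)
  cat <- catalog
  if (zygosity_filter == "hom_only")
    cat <- cat[cat$zygosity == "hom", , drop = FALSE]
  drop_sv <- cat$category == "SV" &
    (!is.na(cat$structure_resolved) & !cat$structure_resolved)
  cat <- cat[!drop_sv, , drop = FALSE]
  counts <- setNames(integer(length(plants)), plants)
  for (pl in plants) {
    ev <- cat[cat$sample == pl, , drop = FALSE]
    hit <- character(0)
    for (i in seq_len(nrow(ev))) {
      g <- genes_affected(ev[i, , drop = FALSE], genes)
      if (exclude_multigene && length(g) >= 2) next
      hit <- union(hit, g)
    }
    counts[pl] <- length(hit)
  }
  counts
}
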