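# Shared fixtures: tiny in-code VCFs, genomes and catalogs.

vcf_fixture_lines <- function(body = character(0), sample = "S1",
                              contigs = c(chr1 = 100000L, chr3 = 100000L)) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"Len\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type\">",
    "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"Mate\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    body)
}

write_vcf_fixture <- function(body, sample = "S1", ...) {
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf_fixture_lines(body, sample, ...), path)
  path
}

# simple retained-records table for classify_records()
records_fixture <- function(sample_id, chrom, pos, ref, alt, zygosity,
                            caller = "snv_indel_caller",
                            sv_type = NA_character_, end_pos = NA_integer_,
                            id = NA_character_, mate_id = NA_character_,
                            sv_length = NA_integer_) {
  n <- length(pos)
  df <- data.frame(
    sample_id = rep_len(sample_id, n), caller = rep_len(caller, n),
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    id = rep_len(id, n), ref = ref, alt = alt,
    end_pos = rep_len(as.integer(end_pos), n),
    sv_type = rep_len(sv_type, n), sv_length = rep_len(sv_length, n),
    af = rep_len(1, n), depth = rep_len(40L, n),
    mate_id = rep_len(mate_id, n), zygosity = rep_len(zygosity, n),
    stringsAsFactors = FALSE)
  df
}

# Independent clustering oracle for merge_complex: pairwise union-find over
# primitives whose inter-change gap is below the threshold (only primitives
# eligible for complexing join).
oracle_clusters <- function(prim, gap_threshold = 10L,
                            max_indel_in_complex = 9L) {
  n <- nrow(prim)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  eligible <- prim$type == "SBS" | abs(prim$net) <= max_indel_in_complex
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (prim$chrom[i] != prim$chrom[j]) next
    if (!eligible[i] || !eligible[j]) next
    lo <- if (prim$start[i] <= prim$start[j]) i else j
    hi <- if (lo == i) j else i
    gap <- prim$start[hi] - prim$end[lo] - 1L
    # an ineligible primitive lying between the pair terminates the cluster
    between <- prim$chrom == prim$chrom[i] &
      prim$start > prim$start[lo] & prim$start < prim$start[hi]
    blocked <- any(between & !eligible)
    if (gap < gap_threshold && !blocked) parent[find(hi)] <- find(lo)
  }
  vapply(seq_len(n), find, integer(1))
}

# Random primitive layout on a short sequence (sorted, non-overlapping).
random_layout <- function(n_max = 8, seq_len_bp = 200) {
  n <- sample(1:n_max, 1)
  rows <- list()
  cur <- 1L
  for (i in seq_len(n)) {
    cur <- cur + sample(0:25, 1)
    type <- sample(c("SBS", "Ins", "Del"), 1)
    if (type == "SBS") {
      rows[[i]] <- data.frame(type = "SBS", chrom = "c", start = cur,
                              end = cur, net = 0L)
      cur <- cur + 1L
    } else if (type == "Ins") {
      net <- sample(1:15, 1)
      rows[[i]] <- data.frame(type = "Ins", chrom = "c", start = cur,
                              end = cur, net = net)
      cur <- cur + 1L
    } else {
      net <- sample(1:15, 1)
      rows[[i]] <- data.frame(type = "Del", chrom = "c", start = cur,
                              end = cur + net - 1L, net = -net)
      cur <- cur + net
    }
  }
  do.call(rbind, rows)
}

small_genome <- function(seed = 101, length = 5e4, n_chrom = 2) {
  make_genome(length, 0.36, seed = seed, n_chrom = n_chrom)
}
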