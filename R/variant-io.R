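# Reading caller-style VCFs, reference FASTA, and the harmonized catalog TSV.

#' Caller identifiers understood by the pipeline
#'
#' Five caller roles are distinguished so that multi-caller augmentation can
#' be attributed per record: a small-variant caller (`snv_indel_caller`,
#' GATK-like), split-read and read-pair SV callers (`sr_caller`, `rp_caller`;
#' Pindel/BreakDancer-like), and two combined-approach SV callers
#' (`combined_caller_a`, `combined_caller_b`; Manta/Lumpy-like).
#'
#' @export
CALLERS <- c("snv_indel_caller", "sr_caller", "rp_caller",
             "combined_caller_a", "combined_caller_b")

# Canonical column layout of a variant-record table.
VARIANT_COLS <- c("sample_id", "caller", "chrom", "pos", "id", "ref", "alt",
                  "end_pos", "sv_type", "sv_length", "af", "depth", "mate_id")

new_variant_records <- function(df) {
  stopifnot(is.data.frame(df), all(VARIANT_COLS %in% names(df)))
  df <- df[, VARIANT_COLS]
  class(df) <- c("variant_records", "data.frame")
  df
}

empty_variant_records <- function() {
  new_variant_records(data.frame(
    sample_id = character(), caller = character(), chrom = character(),
    pos = integer(), id = character(), ref = character(), alt = character(),
    end_pos = integer(), sv_type = character(), sv_length = integer(),
    af = double(), depth = integer(), mate_id = character(),
    stringsAsFactors = FALSE))
}

#' Combine variant-record tables
#'
#' @param ... `variant_records` tables as returned by [read_caller_vcf()].
#' @return a single `variant_records` table.
#' @export
bind_records <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(empty_variant_records())
  new_variant_records(do.call(rbind, lapply(parts, as.data.frame)))
}

validate_variant_records <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$pos < 1)) stop("variant positions must be >= 1")
  bad_end <- !is.na(df$end_pos) & df$end_pos < df$pos
  if (any(bad_end)) stop("end_pos must be >= pos")
  bad_af <- !is.na(df$af) & (df$af < 0 | df$af > 1)
  if (any(bad_af)) stop("allele fractions must lie in [0, 1]")
  invisible(df)
}

# Structural pre-check so that parse failures name the offending line.
precheck_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[[1]], "##fileformat=VCF"))
    stop("not a VCF 4.x file (missing ##fileformat header): ", path)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("malformed VCF line ", i, " in ", path,
           ": expected >= 8 tab-separated fields, found ", length(f))
    if (is.na(suppressWarnings(as.integer(f[[2]]))))
      stop("malformed VCF line ", i, " in ", path,
           ": POS is not an integer ('", f[[2]], "')")
  }
  invisible(length(body))
}

#' Read one caller's VCF into the internal variant-record model
#'
#' Parses a VCF 4.x file (plain text or bgzipped) produced by one caller for
#' one sample and returns a `variant_records` data frame with one row per
#' data line. Symbolic SV records (`<DEL>`, `<INV>`, `<DUP>`) are resolved to
#' a closed 1-based interval using the `END`/`SVLEN` INFO keys; breakend
#' (`SVTYPE=BND`) records are cross-linked through `MATEID` and must occur in
#' mated pairs. The allele fraction is taken as alt-supporting reads / depth
#' from the `AD`/`DP` FORMAT fields when present.
#'
#' @param path path to a VCF file.
#' @param caller one of [CALLERS].
#' @param sample_id sample label attached to every record.
#' @return a `variant_records` data frame (columns `sample_id`, `caller`,
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `end_pos`, `sv_type`, `sv_length`,
#'   `af`, `depth`, `mate_id`).
#' @export
read_caller_vcf <- function(path, caller, sample_id) {
  caller <- match.arg(caller, CALLERS)
  n_body <- precheck_vcf_lines(path)
  if (n_body == 0) return(empty_variant_records())

  v <- suppressWarnings(VariantAnnotation::scanVcf(path)[[1]])
  rr <- v$rowRanges
  n <- length(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- names(rr)
  if (is.null(ids)) ids <- rep(NA_character_, n)
  ids[ids == "."] <- NA_character_
  ref <- as.character(v$REF)
  alt <- vapply(as.list(v$ALT), function(a)
    if (length(a) == 0) NA_character_ else as.character(a[[1]]), character(1))

  info <- v$INFO
  getinfo <- function(key, default) {
    x <- info[[key]]
    if (is.null(x)) return(rep(default, n))
    if (is.list(x)) x <- vapply(x, function(e)
      if (length(e) == 0) default else e[[1]], default)
    x[is.na(x)] <- default
    x
  }
  end_info <- suppressWarnings(as.integer(getinfo("END", NA_integer_)))
  svlen <- suppressWarnings(as.integer(getinfo("SVLEN", NA_integer_)))
  svtype <- as.character(getinfo("SVTYPE", NA_character_))
  mateid <- as.character(getinfo("MATEID", NA_character_))

  # Resolve closed end coordinates: explicit alleles span the REF string;
  # symbolic SVs use END, or POS + |SVLEN| when only SVLEN is given.
  end_pos <- end_info
  explicit <- is.na(svtype) | svtype %in% c("SNV", "MNV", "INS", "DEL", "INDEL")
  symbolic <- !is.na(alt) & grepl("^<", alt)
  bnd <- !is.na(svtype) & svtype == "BND"
  end_pos[!symbolic & !bnd & is.na(end_pos)] <-
    pos[!symbolic & !bnd & is.na(end_pos)] +
    nchar(ref[!symbolic & !bnd & is.na(end_pos)]) - 1L
  need <- symbolic & is.na(end_pos) & !is.na(svlen)
  end_pos[need] <- pos[need] + abs(svlen[need])
  end_pos[bnd] <- pos[bnd]

  # AF from AD (ref, alt counts) and DP.
  depth <- rep(NA_integer_, n)
  af <- rep(NA_real_, n)
  g <- v$GENO
  if (!is.null(g$DP)) depth <- suppressWarnings(as.integer(g$DP[, 1]))
  if (!is.null(g$AD)) {
    ad <- g$AD
    adl <- if (is.list(ad)) ad[, 1] else split(ad, seq_len(n))
    alt_reads <- vapply(adl, function(a)
      if (length(a) >= 2) as.integer(a[[2]]) else NA_integer_, integer(1))
    tot <- ifelse(is.na(depth),
                  vapply(adl, function(a) sum(as.integer(a)), integer(1)),
                  depth)
    af <- ifelse(tot > 0, alt_reads / tot, NA_real_)
  }

  rec <- new_variant_records(data.frame(
    sample_id = rep(sample_id, n), caller = rep(caller, n),
    chrom = chrom, pos = as.integer(pos), id = ids, ref = ref, alt = alt,
    end_pos = as.integer(end_pos), sv_type = svtype,
    sv_length = svlen, af = af, depth = depth, mate_id = mateid,
    stringsAsFactors = FALSE))
  validate_variant_records(rec)

  # Breakends must come in mated pairs within one file.
  if (any(bnd)) {
    b <- rec[bnd, ]
    if (any(is.na(b$mate_id)))
      stop("breakend record(s) without MATEID: ",
           paste(b$id[is.na(b$mate_id)], collapse = ", "))
    orphan <- !(b$mate_id %in% b$id)
    if (any(orphan))
      stop("orphan breakend(s) in ", path, ": ",
           paste(sprintf("%s (mate %s not found)", b$id[orphan],
                         b$mate_id[orphan]), collapse = "; "))
  }
  rec
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return an object of class `genome`: a list with `sequences`
#'   (a [Biostrings::DNAStringSet]), `total_length` (bp) and `gc_content`
#'   (G+C fraction over unambiguous A/C/G/T only).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty or missing FASTA file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("FASTA file contains no sequences: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_from_sequences(seqs)
}

#' Build a `genome` object from sequences
#'
#' @param seqs a named character vector or [Biostrings::DNAStringSet].
#' @return a `genome` object; see [read_fasta()].
#' @export
genome_from_sequences <- function(seqs) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  acgt <- sum(counts)
  if (acgt == 0) stop("genome contains no unambiguous A/C/G/T bases")
  g <- list(sequences = seqs,
            total_length = sum(Biostrings::width(seqs)),
            gc_content = sum(counts[, c("C", "G")]) / acgt)
  class(g) <- "genome"
  g
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d sequence(s), %s bp, GC %.3f\n",
              length(x$sequences), format(x$total_length, big.mark = ","),
              x$gc_content))
  invisible(x)
}

genome_subseq <- function(genome, chrom, start, end) {
  as.character(Biostrings::subseq(genome$sequences[[chrom]], start, end))
}

# ---- catalog TSV -----------------------------------------------------------

CATALOG_COLS <- c("sample", "chrom", "start", "end", "category", "net_length",
                  "zygosity", "source_callers", "sv_kind",
                  "structure_resolved", "components")

CATEGORIES <- c("SBS", "Ins1", "Del1", "Ins2_99", "Del2_99", "DelGE100",
                "SV", "Complex")

empty_catalog <- function() {
  df <- data.frame(
    sample = character(), chrom = character(), start = integer(),
    end = integer(), category = character(), net_length = integer(),
    zygosity = character(), source_callers = character(),
    sv_kind = character(), structure_resolved = logical(),
    components = character(), stringsAsFactors = FALSE)
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

#' Construct a mutation-catalog row
#'
#' @param sample,chrom,start,end event identity and closed 1-based span.
#' @param category one of the eight categories (`SBS`, `Ins1`, `Del1`,
#'   `Ins2_99`, `Del2_99`, `DelGE100`, `SV`, `Complex`).
#' @param net_length signed net length in bp (0 for SBS and SV).
#' @param zygosity `"hom"` or `"het"`.
#' @param source_callers comma-separated caller ids.
#' @param sv_kind `"inversion"`, `"translocation"`, or `"none"`.
#' @param structure_resolved for SV events, whether the overall structure
#'   was deduced; `NA` otherwise.
#' @param components serialized primitive components (`"."` when none).
#' @return a one-row `mutation_catalog` data frame.
#' @export
mutation_event <- function(sample, chrom, start, end, category, net_length = 0L,
                           zygosity = "het", source_callers = "",
                           sv_kind = "none", structure_resolved = NA,
                           components = ".") {
  category <- match.arg(category, CATEGORIES)
  zygosity <- match.arg(zygosity, c("hom", "het"))
  if (category == "Del2_99" && !(-net_length >= 2 && -net_length <= 99))
    stop("Del2_99 requires net_length in [-99, -2], got ", net_length)
  if (category == "DelGE100" && !(-net_length >= 100))
    stop("DelGE100 requires net_length <= -100, got ", net_length)
  if (category == "SV" && sv_kind == "none")
    stop("SV events must carry sv_kind 'inversion' or 'translocation'")
  df <- data.frame(sample = sample, chrom = chrom, start = as.integer(start),
                   end = as.integer(end), category = category,
                   net_length = as.integer(net_length), zygosity = zygosity,
                   source_callers = source_callers, sv_kind = sv_kind,
                   structure_resolved = structure_resolved,
                   components = components, stringsAsFactors = FALSE)
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

as_catalog <- function(df) {
  if (nrow(df) == 0) return(empty_catalog())
  stopifnot(all(CATALOG_COLS %in% names(df)))
  df <- df[, CATALOG_COLS]
  rownames(df) <- NULL
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

#' Write a classified catalog as TSV
#'
#' Fixed column order `sample, chrom, start, end, category, net_length,
#' zygosity, source_callers, sv_kind, structure_resolved, components`;
#' [read_catalog()] inverts it losslessly.
#'
#' @param events a `mutation_catalog` data frame.
#' @param path output TSV path.
#' @export
write_catalog <- function(events, path) {
  events <- as.data.frame(events)
  if (nrow(events) > 0) {
    if (any(is.na(events$category)) ||
        !all(events$category %in% CATEGORIES))
      stop("catalog contains unclassified events; classify before writing")
  } else {
    events <- as.data.frame(empty_catalog())
  }
  out <- events[, CATALOG_COLS]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a catalog TSV written by [write_catalog()]
#'
#' @param path TSV path.
#' @return a `mutation_catalog` data frame.
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(sample = "character", chrom = "character",
                                  start = "integer", end = "integer",
                                  category = "character",
                                  net_length = "integer",
                                  zygosity = "character",
                                  source_callers = "character",
                                  sv_kind = "character",
                                  structure_resolved = "logical",
                                  components = "character"))
  as_catalog(df)
}
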