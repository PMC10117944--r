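# Normalization of filtered variants into mutation events and assignment of
# the eight-category scheme: SBS, Ins1, Del1, Ins2_99, Del2_99, DelGE100,
# SV (inversions/translocations), Complex.

#' Classification configuration
#'
#' @param gap_threshold primitives closer than this many reference bases
#'   (exclusive) merge into one complex event.
#' @param separator_run within a caller-reported multi-base substitution
#'   block, a run of at least this many reference-matching bases is treated
#'   as unmutated sequence separating primitives.
#' @param min_cluster_size a cluster must contain at least this many
#'   primitive changes to be called Complex (default 2; set 3 for the
#'   literal "more than two" reading).
#' @param max_indel_in_complex largest absolute net indel length (bp) that
#'   can participate in a complex cluster; larger indels terminate clusters
#'   and stand alone.
#' @return a `classify_config` list.
#' @export
classify_config <- function(gap_threshold = 10L, separator_run = 2L,
                            min_cluster_size = 2L, max_indel_in_complex = 9L) {
  stopifnot(gap_threshold >= 1, separator_run >= 1, min_cluster_size >= 2)
  structure(list(gap_threshold = as.integer(gap_threshold),
                 separator_run = as.integer(separator_run),
                 min_cluster_size = as.integer(min_cluster_size),
                 max_indel_in_complex = as.integer(max_indel_in_complex)),
            class = "classify_config")
}

#' Net length of an indel with unknown-sequence insertion
#'
#' A putative deletion accompanied by an insertion of unknown sequence is
#' scored by its net difference from the reference: a 10-base deletion with
#' a 3-base insertion is a 7-base deletion (net -7).
#'
#' @param deleted_bp reference bases removed (>= 0).
#' @param inserted_bp bases inserted (>= 0).
#' @return signed net length in bp; negative values are net deletions.
#' @export
net_indel_length <- function(deleted_bp, inserted_bp) {
  stopifnot(deleted_bp >= 0, inserted_bp >= 0)
  if (deleted_bp == 0 && inserted_bp == 0)
    stop("no length change: not an InDel")
  as.integer(inserted_bp - deleted_bp)
}

#' Category of a normalized primitive change
#'
#' @param type `"substitution"`, `"indel"`, `"inversion"` or
#'   `"translocation"`.
#' @param net_length signed net length (required for indels).
#' @return one of the eight category labels (never `"Complex"`, which only
#'   arises from clustering).
#' @export
categorize <- function(type = c("substitution", "indel", "inversion",
                                "translocation"),
                       net_length = 0L) {
  type <- match.arg(type)
  if (type %in% c("inversion", "translocation")) return("SV")
  if (type == "substitution") return("SBS")
  n <- as.integer(net_length)
  if (n == 0L) stop("an indel must have a nonzero net length")
  if (n == 1L) return("Ins1")
  if (n == -1L) return("Del1")
  if (n >= 2L && n <= 99L) return("Ins2_99")
  if (n <= -2L && n >= -99L) return("Del2_99")
  if (n <= -100L) return("DelGE100")
  stop("insertions of 100 bp or more have no category in this scheme ",
       "(net length ", n, ")")
}

# ---- primitive decomposition ----------------------------------------------

# Decompose one explicit-allele record into primitive changes. Returns a data
# frame: type ("SBS"/"Ins"/"Del"), chrom, start, end, net. Trims the common
# prefix/suffix; equal-length remainders are scanned base by base, with
# reference-matching runs separating SBS primitives; unequal-length
# remainders are a single net indel (possibly with unknown inserted
# sequence).
decompose_alleles <- function(chrom, pos, ref, alt) {
  rc <- strsplit(ref, "")[[1]]
  ac <- strsplit(alt, "")[[1]]
  # common prefix
  p <- 0L
  while (p < length(rc) && p < length(ac) && rc[p + 1L] == ac[p + 1L])
    p <- p + 1L
  # common suffix (not overlapping the prefix)
  s <- 0L
  while (s < length(rc) - p && s < length(ac) - p &&
         rc[length(rc) - s] == ac[length(ac) - s])
    s <- s + 1L
  rrem <- rc[seq_len(length(rc) - p - s) + p]
  arem <- ac[seq_len(length(ac) - p - s) + p]
  empty <- data.frame(type = character(), chrom = character(),
                      start = integer(), end = integer(), net = integer(),
                      stringsAsFactors = FALSE)
  if (length(rrem) == 0 && length(arem) == 0) return(empty)
  if (length(rrem) == length(arem)) {
    mism <- which(rrem != arem)
    if (length(mism) == 0) return(empty)
    at <- pos + p + mism - 1L
    return(data.frame(type = "SBS", chrom = chrom, start = at, end = at,
                      net = 0L, stringsAsFactors = FALSE))
  }
  net <- net_indel_length(length(rrem), length(arem))
  if (length(rrem) == 0) {        # pure insertion; anchor at preceding base
    a <- pos + p - 1L
    return(data.frame(type = "Ins", chrom = chrom, start = a, end = a,
                      net = net, stringsAsFactors = FALSE))
  }
  data.frame(type = if (net < 0) "Del" else "Ins", chrom = chrom,
             start = pos + p, end = pos + p + length(rrem) - 1L,
             net = net, stringsAsFactors = FALSE)
}

#' Merge nearby primitive changes into complex events
#'
#' Primitives on one sample/chromosome, sorted by position, merge into one
#' complex-type event when every inter-change gap (reference bases strictly
#' between consecutive primitives) is below `gap_threshold` and the cluster
#' holds at least `min_cluster_size` changes. Indels with |net| greater than
#' `max_indel_in_complex` never join a cluster. Singletons pass through and
#' are categorized individually.
#'
#' @param primitives data frame with columns `type` (`SBS`/`Ins`/`Del`),
#'   `chrom`, `start`, `end`, `net`, position-sorted and non-overlapping.
#' @param config a [classify_config()].
#' @return data frame of events: `chrom`, `start`, `end`, `category`,
#'   `net_length`, `components` (`"."` for simple events, serialized
#'   component list for Complex).
#' @export
merge_complex <- function(primitives, config = classify_config()) {
  cols <- c("chrom", "start", "end", "category", "net_length", "components")
  if (nrow(primitives) == 0)
    return(stats::setNames(data.frame(character(), integer(), integer(),
                                      character(), integer(), character(),
                                      stringsAsFactors = FALSE), cols))
  for (ch in unique(primitives$chrom)) {
    st <- primitives$start[primitives$chrom == ch]
    if (is.unsorted(st)) stop("primitives must be position-sorted per chrom")
  }
  out <- list()
  for (ch in unique(primitives$chrom)) {
    p <- primitives[primitives$chrom == ch, , drop = FALSE]
    eligible <- p$type == "SBS" | abs(p$net) <= config$max_indel_in_complex
    n <- nrow(p)
    cluster <- integer(n)
    cur <- 1L
    cluster[1] <- cur
    if (n > 1) for (i in 2:n) {
      gap <- p$start[i] - p$end[i - 1L] - 1L
      joinable <- eligible[i] && eligible[i - 1L] && gap < config$gap_threshold
      if (!joinable) cur <- cur + 1L
      cluster[i] <- cur
    }
    for (cl in unique(cluster)) {
      q <- p[cluster == cl, , drop = FALSE]
      if (nrow(q) >= config$min_cluster_size) {
        comp <- paste(sprintf("%s@%d:%+d", q$type, q$start, q$net),
                      collapse = ";")
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = min(q$start), end = max(q$end),
          category = "Complex", net_length = sum(q$net), components = comp,
          stringsAsFactors = FALSE)
      } else {
        for (r in seq_len(nrow(q))) {
          cat1 <- categorize(if (q$type[r] == "SBS") "substitution" else
            "indel", q$net[r])
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, start = q$start[r], end = q$end[r], category = cat1,
            net_length = q$net[r], components = ".", stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

parse_components <- function(components) {
  if (is.na(components) || components == ".") return(
    data.frame(type = character(), start = integer(), net = integer()))
  parts <- strsplit(components, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Za-z]+)@([0-9]+):([+-][0-9]+)$", parts))
  data.frame(type = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)),
             net = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Subclassify a complex event by its InDel content
#'
#' @param event a one-row `mutation_catalog` entry with category `Complex`,
#'   or its serialized `components` string.
#' @return `"no_indel"`, `"one_indel"` or `"two_plus_indels"`.
#' @export
complexity_subclass <- function(event) {
  if (is.data.frame(event)) {
    if (nrow(event) != 1 || event$category != "Complex")
      stop("complexity_subclass() requires a single Complex event")
    comp <- event$components
  } else comp <- event
  k <- sum(parse_components(comp)$type != "SBS")
  if (k == 0) "no_indel" else if (k == 1) "one_indel" else "two_plus_indels"
}

#' Extract the rearrangement subset of a catalog
#'
#' Rearrangements are structural variations plus deletions of 100 bp or
#' more, both interpreted as rejoining of two distant double-strand breaks.
#'
#' @param catalog a `mutation_catalog`.
#' @return the subset with category `SV` or `DelGE100`.
#' @export
group_rearrangements <- function(catalog) {
  as_catalog(catalog[catalog$category %in% c("SV", "DelGE100"), , drop = FALSE])
}

# ---- full classification of filtered records -------------------------------

# Collapse duplicate detections of one site across callers; keeps one
# representative record and a comma-joined caller list.
dedupe_callers <- function(records, tolerance = 10L) {
  if (nrow(records) == 0) {
    records$source_callers <- character(0)
    return(records)
  }
  keys <- paste(records$sample_id, site_keys(records, tolerance), sep = "|")
  reps <- !duplicated(keys)
  callers <- vapply(split(records$caller, keys), function(cc)
    paste(sort(unique(cc)), collapse = ","), character(1))
  out <- records[reps, , drop = FALSE]
  out$source_callers <- unname(callers[keys[reps]])
  rownames(out) <- NULL
  out
}

#' Classify filtered records into a mutation catalog
#'
#' Takes the retained, zygosity-annotated records from
#' [apply_site_filters()], collapses multi-caller duplicates, decomposes
#' explicit-allele records into primitive changes, applies the complex-event
#' clustering rule, resolves symbolic and breakend structural records, and
#' returns the classified catalog.
#'
#' @param records retained `variant_records` with a `zygosity` column.
#' @param config a [classify_config()].
#' @param sv_tolerance bp tolerance for cross-caller SV endpoint matching.
#' @return a `mutation_catalog` data frame.
#' @export
classify_records <- function(records, config = classify_config(),
                             sv_tolerance = 10L) {
  if (nrow(records) == 0) return(empty_catalog())
  if (is.null(records$zygosity))
    stop("records must carry a zygosity column; run apply_site_filters()")
  records <- dedupe_callers(records, sv_tolerance)
  symbolic <- !is.na(records$alt) & grepl("^<", records$alt)
  bnd <- !is.na(records$sv_type) & records$sv_type == "BND"
  expl <- records[!symbolic & !bnd, , drop = FALSE]
  events <- list()

  # explicit alleles: decompose and cluster per sample+chrom
  if (nrow(expl) > 0) {
    for (sm in unique(expl$sample_id)) {
      e <- expl[expl$sample_id == sm, , drop = FALSE]
      e <- e[order(e$chrom, e$pos), , drop = FALSE]
      prim <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
        d <- decompose_alleles(e$chrom[i], e$pos[i], e$ref[i], e$alt[i])
        if (nrow(d) > 0) {
          d$zygosity <- e$zygosity[i]
          d$source_callers <- e$source_callers[i]
        } else {
          d$zygosity <- character(0); d$source_callers <- character(0)
        }
        d
      }))
      if (is.null(prim) || nrow(prim) == 0) next
      prim <- prim[order(prim$chrom, prim$start), , drop = FALSE]
      ev <- merge_complex(prim[, c("type", "chrom", "start", "end", "net")],
                          config)
      # re-attach zygosity/callers by matching component spans
      ev$sample <- sm
      ev$zygosity <- vapply(seq_len(nrow(ev)), function(i) {
        inside <- prim$chrom == ev$chrom[i] & prim$start >= ev$start[i] &
          prim$start <= ev$end[i]
        zz <- prim$zygosity[inside]
        names(sort(table(zz), decreasing = TRUE))[1]
      }, character(1))
      ev$source_callers <- vapply(seq_len(nrow(ev)), function(i) {
        inside <- prim$chrom == ev$chrom[i] & prim$start >= ev$start[i] &
          prim$start <= ev$end[i]
        paste(sort(unique(unlist(strsplit(prim$source_callers[inside], ",")))),
              collapse = ",")
      }, character(1))
      ev$sv_kind <- "none"
      ev$structure_resolved <- NA
      names(ev)[names(ev) == "net_length"] <- "net_length"
      events[[length(events) + 1L]] <- ev[, c("sample", "chrom", "start",
                                              "end", "category", "net_length",
                                              "zygosity", "source_callers",
                                              "sv_kind", "structure_resolved",
                                              "components")]
    }
  }

  # symbolic SVs
  sym <- records[symbolic, , drop = FALSE]
  if (nrow(sym) > 0) {
    kind <- sub("^<([A-Z]+)>$", "\\1", sym$alt)
    if (any(!kind %in% c("DEL", "INV")))
      stop("unsupported symbolic allele(s): ",
           paste(unique(kind[!kind %in% c("DEL", "INV")]), collapse = ", "))
    for (i in seq_len(nrow(sym))) {
      if (kind[i] == "DEL") {
        # POS anchors the base before the deletion; END is its last base
        start <- sym$pos[i] + 1L
        end <- sym$end_pos[i]
        net <- -(end - start + 1L)
        events[[length(events) + 1L]] <- data.frame(
          sample = sym$sample_id[i], chrom = sym$chrom[i], start = start,
          end = end, category = categorize("indel", net), net_length = net,
          zygosity = sym$zygosity[i], source_callers = sym$source_callers[i],
          sv_kind = "none", structure_resolved = NA, components = ".",
          stringsAsFactors = FALSE)
      } else {
        events[[length(events) + 1L]] <- data.frame(
          sample = sym$sample_id[i], chrom = sym$chrom[i],
          start = sym$pos[i] + 1L, end = sym$end_pos[i], category = "SV",
          net_length = 0L, zygosity = sym$zygosity[i],
          source_callers = sym$source_callers[i], sv_kind = "inversion",
          structure_resolved = FALSE, components = ".",
          stringsAsFactors = FALSE)
      }
    }
  }

  # breakend pairs: one SV event per mated pair
  bd <- records[bnd, , drop = FALSE]
  if (nrow(bd) > 0) {
    for (sm in unique(bd$sample_id)) {
      b <- bd[bd$sample_id == sm, , drop = FALSE]
      seen <- character(0)
      for (i in seq_len(nrow(b))) {
        if (b$id[i] %in% seen) next
        j <- match(b$mate_id[i], b$id)
        if (is.na(j))
          stop("orphan breakend in classified records: ", b$id[i])
        seen <- c(seen, b$id[i], b$id[j])
        inter <- b$chrom[i] != b$chrom[j]
        # canonical junction order: by chromosome, then position
        jo <- order(b$chrom[c(i, j)], b$pos[c(i, j)])
        jj <- c(i, j)[jo]
        comp <- paste(sprintf("J@%s:%d", b$chrom[jj], b$pos[jj]),
                      collapse = ";")
        events[[length(events) + 1L]] <- data.frame(
          sample = sm, chrom = b$chrom[jj[1]],
          start = if (inter) b$pos[jj[1]] else min(b$pos[c(i, j)]),
          end = if (inter) b$pos[jj[1]] else max(b$pos[c(i, j)]),
          category = "SV", net_length = 0L, zygosity = b$zygosity[i],
          source_callers = b$source_callers[i],
          sv_kind = if (inter) "translocation" else "inversion",
          structure_resolved = FALSE, components = comp,
          stringsAsFactors = FALSE)
      }
    }
  }

  if (length(events) == 0) return(empty_catalog())
  cat <- do.call(rbind, events)
  cat <- cat[order(cat$sample, cat$chrom, cat$start), , drop = FALSE]
  as_catalog(cat)
}
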