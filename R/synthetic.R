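# Synthetic-data generation: reference genomes, gene models, ground-truth
# per-plant mutation catalogs per treatment profile, noisy multi-caller VCF
# emissions, and simulated survival assays. Everything is reproducible from
# a single seed.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.null(seed) && abs(seed) >= 2^31) stop("seed must fit a 32-bit integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage sub-seed derived from one global seed.
substream <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% (2^31 - 1))
}

#' Generate a random reference genome
#'
#' Bases are i.i.d. with P(G) + P(C) equal to the target GC content
#' (default 0.36, the composition of the Arabidopsis TAIR10 reference).
#'
#' @param length total length in bp (>= 10 kb).
#' @param gc target GC fraction in (0, 1).
#' @param seed RNG seed.
#' @param n_chrom number of chromosomes (length is split evenly).
#' @return a `genome` object.
#' @export
make_genome <- function(length, gc = 0.36, seed = NULL, n_chrom = 1L) {
  if (length < 1e4) stop("genome length must be at least 10 kb")
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly in (0, 1)")
  with_seed(seed, {
    per <- rep(length %/% n_chrom, n_chrom)
    per[n_chrom] <- per[n_chrom] + length %% n_chrom
    seqs <- vapply(per, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = ""), character(1))
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    genome_from_sequences(seqs)
  })
}

#' Write a genome as FASTA
#'
#' @param genome a `genome` object.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequences, path)
  invisible(path)
}

#' Generate non-overlapping protein-coding gene models
#'
#' @param genome a `genome` object.
#' @param n_genes number of genes to place.
#' @param mean_length mean gene length in bp.
#' @param seed RNG seed.
#' @param packed_block optional list `(n, span, chrom, start)` placing `n`
#'   contiguous genes inside a `span`-bp block (multi-gene-deletion
#'   fixtures).
#' @return gene-model data frame as from [read_gene_models()].
#' @export
make_gene_models <- function(genome, n_genes, mean_length = 2000,
                             seed = NULL, packed_block = NULL) {
  with_seed(seed, {
    chroms <- names(genome$sequences)
    lens <- setNames(Biostrings::width(genome$sequences), chroms)
    occupied <- lapply(chroms, function(x) cbind(integer(0), integer(0)))
    names(occupied) <- chroms
    rows <- list()
    place <- function(chrom, start, end, id) {
      occ <- occupied[[chrom]]
      if (any(start <= occ[, 2] & end >= occ[, 1]))
        return(FALSE)
      occupied[[chrom]] <<- rbind(occ, c(start, end))
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = id, chrom = chrom, start = start, end = end,
        strand = sample(c("+", "-"), 1), biotype = "protein_coding",
        stringsAsFactors = FALSE)
      TRUE
    }
    if (!is.null(packed_block)) {
      gl <- max(50L, packed_block$span %/% packed_block$n - 10L)
      for (i in seq_len(packed_block$n)) {
        s <- packed_block$start + (i - 1L) * (gl + 10L)
        if (!place(packed_block$chrom, s, s + gl - 1L,
                   sprintf("packed_g%03d", i)))
          stop("cannot place packed gene block without overlap")
      }
    }
    for (i in seq_len(n_genes)) {
      ok <- FALSE
      for (try in 1:200) {
        chrom <- sample(chroms, 1)
        gl <- max(200L, as.integer(round(rnorm(1, mean_length,
                                               mean_length / 4))))
        if (gl >= lens[[chrom]]) next
        s <- sample.int(lens[[chrom]] - gl, 1)
        if (place(chrom, s, s + gl - 1L, sprintf("gene%05d", i))) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("cannot place ", n_genes, " genes without overlap")
    }
    gm <- do.call(rbind, rows)
    gm[order(gm$chrom, gm$start), , drop = FALSE]
  })
}

#' Write gene models as GFF3
#'
#' @param genes gene-model data frame.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0)
    writeLines(sprintf("%s\tradmut\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                       genes$chrom, genes$start, genes$end, genes$strand,
                       genes$gene_id, genes$biotype), con)
  invisible(path)
}

# ---- treatment profiles ----------------------------------------------------

#' Define a treatment profile for catalog simulation
#'
#' @param label profile name.
#' @param events_per_plant Poisson mean of mutation events per plant.
#' @param category_mix named 8-way probability vector over the categories.
#' @param sbs_class_mix named 6-way probability vector over the merged SBS
#'   classes (`GC_AT`, `AT_GC`, `GC_TA`, `GC_CG`, `AT_TA`, `AT_CG`).
#' @param hom_probability probability an event is homozygous (M2
#'   expectation 1/3).
#' @param max_large_del cap on large-deletion size (bp); also capped at
#'   1/20 of the genome at simulation time.
#' @return a `treatment_profile` list.
#' @export
treatment_profile <- function(label, events_per_plant, category_mix,
                              sbs_class_mix, hom_probability = 1 / 3,
                              max_large_del = 400000L) {
  stopifnot(setequal(names(category_mix), CATEGORIES),
            setequal(names(sbs_class_mix), SBS_CLASSES),
            events_per_plant > 0, hom_probability >= 0, hom_probability <= 1)
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix must sum to 1")
  if (abs(sum(sbs_class_mix) - 1) > 1e-9)
    stop("sbs_class_mix must sum to 1")
  structure(list(label = label, events_per_plant = events_per_plant,
                 category_mix = category_mix[CATEGORIES],
                 sbs_class_mix = sbs_class_mix[SBS_CLASSES],
                 hom_probability = hom_probability,
                 max_large_del = as.integer(max_large_del)),
            class = "treatment_profile")
}

#' Default treatment profiles
#'
#' Four material-radiation combinations with qualitative contrasts typical
#' of comparative plant mutagenesis: carbon ions enriched for 2-99 bp
#' deletions and rearrangements, gamma rays enriched for SBS, dry-seed
#' treatments showing elevated A:T->T:A transversions. Mean event counts
#' per plant and per-plant rearrangement rates follow the published group
#' sizes; the category and class vectors are illustrative, not estimates.
#'
#' @return named list of [treatment_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    gamma_dry = treatment_profile(
      "gamma_dry", events_per_plant = 73,
      category_mix = c(SBS = .60, Ins1 = .04, Del1 = .12, Ins2_99 = .03,
                       Del2_99 = .09, DelGE100 = .005, SV = .006,
                       Complex = .109),
      sbs_class_mix = c(GC_AT = .28, AT_GC = .20, GC_TA = .12, GC_CG = .08,
                        AT_TA = .22, AT_CG = .10)),
    gamma_seedling = treatment_profile(
      "gamma_seedling", events_per_plant = 41,
      category_mix = c(SBS = .55, Ins1 = .05, Del1 = .10, Ins2_99 = .03,
                       Del2_99 = .12, DelGE100 = .010, SV = .012,
                       Complex = .128),
      sbs_class_mix = c(GC_AT = .32, AT_GC = .18, GC_TA = .17, GC_CG = .13,
                        AT_TA = .12, AT_CG = .08)),
    carbon_dry = treatment_profile(
      "carbon_dry", events_per_plant = 35,
      category_mix = c(SBS = .40, Ins1 = .04, Del1 = .10, Ins2_99 = .04,
                       Del2_99 = .25, DelGE100 = .022, SV = .024,
                       Complex = .124),
      sbs_class_mix = c(GC_AT = .25, AT_GC = .18, GC_TA = .11, GC_CG = .07,
                        AT_TA = .27, AT_CG = .12)),
    carbon_seedling = treatment_profile(
      "carbon_seedling", events_per_plant = 21,
      category_mix = c(SBS = .42, Ins1 = .04, Del1 = .08, Ins2_99 = .03,
                       Del2_99 = .20, DelGE100 = .034, SV = .037,
                       Complex = .159),
      sbs_class_mix = c(GC_AT = .30, AT_GC = .17, GC_TA = .16, GC_CG = .14,
                        AT_TA = .13, AT_CG = .10)))
}

# ---- catalog simulation ----------------------------------------------------

random_base <- function(exclude = NULL) {
  sample(setdiff(c("A", "C", "G", "T"), exclude), 1)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

log_uniform_int <- function(n, lo, hi) {
  as.integer(round(exp(runif(n, log(lo), log(hi)))))
}

# Find a position on `chrom` whose reference base belongs to `bases`.
pick_base_pos <- function(genome, chrom, lo, hi, bases) {
  seqc <- genome$sequences[[chrom]]
  for (try in 1:500) {
    p <- sample(seq.int(lo, hi), 1)
    b <- as.character(Biostrings::subseq(seqc, p, p))
    if (b %in% bases) return(list(pos = p, base = b))
  }
  stop("could not find a ", paste(bases, collapse = "/"), " base")
}

#' Simulate a ground-truth mutation catalog for one treatment group
#'
#' Event counts are Poisson per plant; categories, SBS classes, deletion
#' sizes and positions are drawn from the profile; zygosity is Bernoulli
#' with the profile's homozygous probability; complex events are built as
#' clusters of 2-4 substitutions/short indels with inter-change gaps below
#' the 10 bp clustering rule. Events within a plant are kept at least
#' 200 bp apart so that independent events never co-cluster.
#'
#' @param profile a [treatment_profile()].
#' @param n_plants number of M2 plants.
#' @param genome a `genome` object (2 chromosomes enable translocations).
#' @param seed RNG seed.
#' @param plant_prefix sample-id prefix.
#' @return a `synthetic_truth` list: `events` (truth catalog with emission
#'   detail columns), `primitives` (explicit-allele VCF-level table),
#'   `svrecords` (symbolic/breakend VCF-level table), `genome`, `profile`,
#'   `plants`, `seed`.
#' @export
simulate_catalog <- function(profile, n_plants, genome, seed = NULL,
                             plant_prefix = profile$label) {
  with_seed(seed, {
    chroms <- names(genome$sequences)
    lens <- setNames(Biostrings::width(genome$sequences), chroms)
    max_del <- min(profile$max_large_del, genome$total_length %/% 20)
    plants <- sprintf("%s_p%02d", plant_prefix, seq_len(n_plants))
    events <- list(); prims <- list(); svs <- list()
    eid <- 0L
    for (pl in plants) {
      n <- rpois(1, profile$events_per_plant)
      occ <- lapply(chroms, function(x) cbind(integer(0), integer(0)))
      names(occ) <- chroms
      reserve <- function(chrom, s, e, pad = 200L) {
        o <- occ[[chrom]]
        if (any(s - pad <= o[, 2] & e + pad >= o[, 1])) return(FALSE)
        occ[[chrom]] <<- rbind(o, c(s, e))
        TRUE
      }
      cats <- sample(CATEGORIES, n, replace = TRUE,
                     prob = profile$category_mix)
      for (ci in seq_len(n)) {
        eid <- eid + 1L
        id <- sprintf("ev%05d", eid)
        zyg <- if (runif(1) < profile$hom_probability) "hom" else "het"
        cat1 <- cats[ci]
        placed <- FALSE
        for (try in 1:300) {
          chrom <- sample(chroms, 1)
          L <- lens[[chrom]]
          if (cat1 == "SBS") {
            cls <- sample(SBS_CLASSES, 1, prob = profile$sbs_class_mix)
            orig <- if (startsWith(cls, "GC")) c("G", "C") else c("A", "T")
            bp <- pick_base_pos(genome, chrom, 100L, L - 100L, orig)
            if (!reserve(chrom, bp$pos, bp$pos)) next
            alt <- sbs_alt_for_class(bp$base, cls)
            events[[eid]] <- truth_row(id, pl, chrom, bp$pos, bp$pos, "SBS",
                                       0L, zyg)
            prims[[length(prims) + 1L]] <- data.frame(
              event_id = id, sample = pl, chrom = chrom, pos = bp$pos,
              ref = bp$base, alt = alt, category = "SBS", zygosity = zyg,
              stringsAsFactors = FALSE)
            placed <- TRUE
          } else if (cat1 %in% c("Ins1", "Ins2_99")) {
            nlen <- if (cat1 == "Ins1") 1L else log_uniform_int(1, 2L, 99L)
            a <- sample.int(L - 200L, 1) + 100L
            if (!reserve(chrom, a, a)) next
            base <- genome_subseq(genome, chrom, a, a)
            events[[eid]] <- truth_row(id, pl, chrom, a, a, cat1, nlen, zyg)
            prims[[length(prims) + 1L]] <- data.frame(
              event_id = id, sample = pl, chrom = chrom, pos = a,
              ref = base, alt = paste0(base, random_seq(nlen)),
              category = cat1, zygosity = zyg, stringsAsFactors = FALSE)
            placed <- TRUE
          } else if (cat1 %in% c("Del1", "Del2_99", "DelGE100")) {
            nlen <- switch(cat1, Del1 = 1L,
                           Del2_99 = log_uniform_int(1, 2L, 99L),
                           DelGE100 = log_uniform_int(1, 100L, max_del))
            s <- sample.int(L - nlen - 400L, 1) + 200L
            e <- s + nlen - 1L
            if (!reserve(chrom, s, e)) next
            events[[eid]] <- truth_row(id, pl, chrom, s, e, cat1, -nlen, zyg)
            if (cat1 == "DelGE100") {
              base <- genome_subseq(genome, chrom, s - 1L, s - 1L)
              svs[[length(svs) + 1L]] <- data.frame(
                event_id = id, sample = pl, chrom = chrom, pos = s - 1L,
                ref = base, alt = "<DEL>", end = e, svtype = "DEL",
                svlen = -nlen, mate_chrom = NA_character_,
                mate_pos = NA_integer_, category = cat1, zygosity = zyg,
                stringsAsFactors = FALSE)
            } else {
              prims[[length(prims) + 1L]] <- data.frame(
                event_id = id, sample = pl, chrom = chrom, pos = s - 1L,
                ref = genome_subseq(genome, chrom, s - 1L, e),
                alt = genome_subseq(genome, chrom, s - 1L, s - 1L),
                category = cat1, zygosity = zyg, stringsAsFactors = FALSE)
            }
            placed <- TRUE
          } else if (cat1 == "Complex") {
            k <- sample(2:4, 1)
            types <- sample(c("SBS", "Ins", "Del"), k, replace = TRUE,
                            prob = c(.6, .2, .2))
            gaps <- sample(1:8, k, replace = TRUE)
            s0 <- sample.int(L - 600L, 1) + 300L
            comp <- list(); cur <- s0
            for (j in seq_len(k)) {
              t1 <- types[j]
              if (t1 == "SBS") {
                comp[[j]] <- list(type = "SBS", s = cur, e = cur, net = 0L)
                cur <- cur + 1L + gaps[j]
              } else if (t1 == "Ins") {
                nl <- sample(1:8, 1)
                comp[[j]] <- list(type = "Ins", s = cur, e = cur, net = nl)
                cur <- cur + 1L + gaps[j]
              } else {
                nl <- sample(1:8, 1)
                comp[[j]] <- list(type = "Del", s = cur, e = cur + nl - 1L,
                                  net = -nl)
                cur <- cur + nl + gaps[j]
              }
            }
            s <- comp[[1]]$s; e <- comp[[k]]$e
            if (!reserve(chrom, s, e)) next
            compstr <- paste(vapply(comp, function(cc)
              sprintf("%s@%d:%+d", cc$type, cc$s, cc$net), character(1)),
              collapse = ";")
            net <- sum(vapply(comp, function(cc) cc$net, integer(1)))
            events[[eid]] <- truth_row(id, pl, chrom, s, e, "Complex",
                                       net, zyg, components = compstr)
            for (cc in comp) {
              if (cc$type == "SBS") {
                b <- genome_subseq(genome, chrom, cc$s, cc$s)
                prims[[length(prims) + 1L]] <- data.frame(
                  event_id = id, sample = pl, chrom = chrom, pos = cc$s,
                  ref = b, alt = random_base(b), category = "Complex",
                  zygosity = zyg, stringsAsFactors = FALSE)
              } else if (cc$type == "Ins") {
                b <- genome_subseq(genome, chrom, cc$s, cc$s)
                prims[[length(prims) + 1L]] <- data.frame(
                  event_id = id, sample = pl, chrom = chrom, pos = cc$s,
                  ref = b, alt = paste0(b, random_seq(cc$net)),
                  category = "Complex", zygosity = zyg,
                  stringsAsFactors = FALSE)
              } else {
                prims[[length(prims) + 1L]] <- data.frame(
                  event_id = id, sample = pl, chrom = chrom, pos = cc$s - 1L,
                  ref = genome_subseq(genome, chrom, cc$s - 1L, cc$e),
                  alt = genome_subseq(genome, chrom, cc$s - 1L, cc$s - 1L),
                  category = "Complex", zygosity = zyg,
                  stringsAsFactors = FALSE)
              }
            }
            placed <- TRUE
          } else {  # SV
            kind <- if (length(chroms) >= 2 && runif(1) < 0.5)
              "translocation" else "inversion"
            if (kind == "inversion") {
              span <- log_uniform_int(1, 1000L, min(50000L, L %/% 10))
              s <- sample.int(L - span - 400L, 1) + 200L
              e <- s + span - 1L
              if (!reserve(chrom, s, e)) next
              base <- genome_subseq(genome, chrom, s - 1L, s - 1L)
              events[[eid]] <- truth_row(id, pl, chrom, s, e, "SV", 0L, zyg,
                                         sv_kind = "inversion",
                                         structure_resolved = FALSE)
              svs[[length(svs) + 1L]] <- data.frame(
                event_id = id, sample = pl, chrom = chrom, pos = s - 1L,
                ref = base, alt = "<INV>", end = e, svtype = "INV",
                svlen = NA_integer_, mate_chrom = NA_character_,
                mate_pos = NA_integer_, category = "SV", zygosity = zyg,
                stringsAsFactors = FALSE)
            } else {
              chrom2 <- sample(setdiff(chroms, chrom), 1)
              p1 <- sample.int(lens[[chrom]] - 400L, 1) + 200L
              p2 <- sample.int(lens[[chrom2]] - 400L, 1) + 200L
              if (!reserve(chrom, p1, p1)) next
              # canonical junction order: by chromosome, then position
              jc <- c(chrom, chrom2); jp <- c(p1, p2)
              jo <- order(jc, jp)
              compstr <- paste(sprintf("J@%s:%d", jc[jo], jp[jo]),
                               collapse = ";")
              events[[eid]] <- truth_row(id, pl, jc[jo][1], jp[jo][1],
                                         jp[jo][1], "SV", 0L,
                                         zyg, sv_kind = "translocation",
                                         structure_resolved = FALSE,
                                         components = compstr)
              b1 <- genome_subseq(genome, chrom, p1, p1)
              b2 <- genome_subseq(genome, chrom2, p2, p2)
              svs[[length(svs) + 1L]] <- data.frame(
                event_id = c(paste0(id, "_1"), paste0(id, "_2")),
                sample = pl, chrom = c(chrom, chrom2), pos = c(p1, p2),
                ref = c(b1, b2),
                alt = c(sprintf("%s]%s:%d]", b1, chrom2, p2),
                        sprintf("%s]%s:%d]", b2, chrom, p1)),
                end = c(p1, p2), svtype = "BND", svlen = NA_integer_,
                mate_chrom = c(chrom2, chrom), mate_pos = c(p2, p1),
                category = "SV", zygosity = zyg, stringsAsFactors = FALSE)
            }
            placed <- TRUE
          }
          if (placed) break
        }
        if (!placed) stop("could not place event ", id, " (", cat1, ")")
      }
    }
    ev <- if (length(events)) do.call(rbind, events) else NULL
    truth <- list(
      events = ev,
      primitives = if (length(prims)) do.call(rbind, prims) else NULL,
      svrecords = if (length(svs)) do.call(rbind, svs) else NULL,
      genome = genome, profile = profile, plants = plants, seed = seed)
    class(truth) <- "synthetic_truth"
    truth
  })
}

sbs_alt_for_class <- function(ref, cls) {
  # class names encode original-pair -> substituted-pair on the purine-
  # labeled strand; e.g. GC_AT means G->A on one strand / C->T on the other
  switch(cls,
         GC_AT = c(G = "A", C = "T")[ref],
         AT_GC = c(A = "G", T = "C")[ref],
         GC_TA = c(G = "T", C = "A")[ref],
         GC_CG = c(G = "C", C = "G")[ref],
         AT_TA = c(A = "T", T = "A")[ref],
         AT_CG = c(A = "C", T = "G")[ref])[[1]]
}

truth_row <- function(id, sample, chrom, start, end, category, net, zyg,
                      sv_kind = "none", structure_resolved = NA,
                      components = ".") {
  data.frame(event_id = id, sample = sample, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             category = category, net_length = as.integer(net),
             zygosity = zyg, source_callers = "truth", sv_kind = sv_kind,
             structure_resolved = structure_resolved,
             components = components, stringsAsFactors = FALSE)
}

#' Extract the truth catalog from a `synthetic_truth`
#'
#' @param truth a `synthetic_truth`.
#' @return a `mutation_catalog`.
#' @export
truth_catalog <- function(truth) {
  if (is.null(truth$events)) return(empty_catalog())
  as_catalog(truth$events[, CATALOG_COLS])
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> profile '%s': %d plants, %d events\n",
              x$profile$label, length(x$plants),
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

# ---- caller emission -------------------------------------------------------

#' Emission noise settings
#'
#' @param af_depth when `TRUE`, depths are Poisson and alt-read counts
#'   binomial around the zygosity-determined allele fraction (0.5 het,
#'   1.0 hom); when `FALSE`, allele fractions are exact.
#' @param depth mean (or fixed) sequencing depth.
#' @param fp_shared_rate expected number of shared false-positive sites per
#'   sample (each injected into >= 2 samples, to be removed by the
#'   recurrence filter).
#' @param sensitivity named list caller -> detection probability (scalar or
#'   named per-category vector); unnamed default applies to all callers.
#' @return an `emission_noise` list.
#' @export
emission_noise <- function(af_depth = FALSE, depth = 40L,
                           fp_shared_rate = 0, sensitivity = 1) {
  structure(list(af_depth = af_depth, depth = as.integer(depth),
                 fp_shared_rate = fp_shared_rate, sensitivity = sensitivity),
            class = "emission_noise")
}

# Which categories each caller can detect.
CALLER_CAPABILITIES <- list(
  snv_indel_caller = c("SBS", "Ins1", "Del1", "Ins2_99", "Del2_99",
                       "Complex"),
  sr_caller = c("DelGE100", "SV"),
  rp_caller = c("DelGE100", "SV"),
  combined_caller_a = c("DelGE100", "SV"),
  combined_caller_b = c("DelGE100", "SV"))

caller_sensitivity <- function(noise, caller, category) {
  s <- noise$sensitivity
  if (is.list(s)) s <- if (!is.null(s[[caller]])) s[[caller]] else 1
  if (length(s) > 1 && !is.null(names(s)))
    s <- if (category %in% names(s)) s[[category]] else 1
  as.numeric(s)
}

sample_reads <- function(n, zygosity, noise) {
  target <- ifelse(zygosity == "hom", 1.0, 0.5)
  if (noise$af_depth) {
    depth <- pmax(10L, rpois(n, noise$depth))
    alt <- rbinom(n, depth, target)
  } else {
    depth <- rep(noise$depth, n)
    alt <- as.integer(round(target * depth))
  }
  list(depth = depth, alt = alt)
}

vcf_header <- function(genome, sample) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"Breakend mate\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$sequences),
            Biostrings::width(genome$sequences)),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
}

#' Emit per-sample, per-caller VCF files from a synthetic truth
#'
#' Each caller sees the event categories it is capable of (a GATK-like
#' small-variant caller for SBS/indels/complex components; SV callers for
#' large deletions, inversions and translocations), thinned by its
#' per-category sensitivity. Allele fractions follow the zygosity (0.5/1.0)
#' with optional binomial read-sampling noise, and shared false-positive
#' SNV sites can be injected across two or more samples.
#'
#' @param truth a `synthetic_truth` from [simulate_catalog()].
#' @param dir output directory (created if needed).
#' @param callers subset of [CALLERS] to emit.
#' @param noise an [emission_noise()].
#' @param seed RNG seed.
#' @return list: `manifest` (sample, caller, path), `fp_log` (injected
#'   shared false positives with their sample lists).
#' @export
emit_caller_outputs <- function(truth, dir,
                                callers = c("snv_indel_caller",
                                            "combined_caller_a"),
                                noise = emission_noise(), seed = NULL) {
  callers <- match.arg(callers, CALLERS, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    manifest <- list(); fp_rows <- list()
    # shared false positives: site list, each assigned to >= 2 samples
    n_fp <- if (noise$fp_shared_rate > 0)
      rpois(1, noise$fp_shared_rate * length(truth$plants)) else 0L
    fp_sites <- NULL
    if (n_fp > 0 && length(truth$plants) >= 2) {
      chroms <- names(truth$genome$sequences)
      lens <- setNames(Biostrings::width(truth$genome$sequences), chroms)
      fp_sites <- do.call(rbind, lapply(seq_len(n_fp), function(i) {
        ch <- sample(chroms, 1)
        p <- sample.int(lens[[ch]] - 200L, 1) + 100L
        b <- genome_subseq(truth$genome, ch, p, p)
        k <- sample(2:min(3, length(truth$plants)), 1)
        data.frame(chrom = ch, pos = p, ref = b, alt = random_base(b),
                   samples = paste(sample(truth$plants, k), collapse = ","),
                   stringsAsFactors = FALSE)
      }))
      fp_rows <- fp_sites
    }
    for (pl in truth$plants) {
      for (caller in callers) {
        caps <- CALLER_CAPABILITIES[[caller]]
        lines <- character(0)
        meta <- list()
        # explicit primitives
        pr <- truth$primitives
        if (!is.null(pr)) {
          pr <- pr[pr$sample == pl & pr$category %in% caps, , drop = FALSE]
          if (nrow(pr) > 0) {
            sens <- vapply(pr$category, function(cc)
              caller_sensitivity(noise, caller, cc), numeric(1))
            keep <- runif(nrow(pr)) < sens
            pr <- pr[keep, , drop = FALSE]
          }
          if (nrow(pr) > 0)
            meta[[length(meta) + 1L]] <- data.frame(
              chrom = pr$chrom, pos = pr$pos, id = ".", ref = pr$ref,
              alt = pr$alt, info = ".", zygosity = pr$zygosity,
              stringsAsFactors = FALSE)
        }
        # symbolic / breakend records
        sv <- truth$svrecords
        if (!is.null(sv)) {
          sv <- sv[sv$sample == pl & sv$category %in% caps, , drop = FALSE]
          if (nrow(sv) > 0) {
            # breakend mates live or die together
            base_id <- sub("_[12]$", "", sv$event_id)
            keep_ev <- vapply(unique(base_id), function(be) {
              cc <- sv$category[base_id == be][1]
              runif(1) < caller_sensitivity(noise, caller, cc)
            }, logical(1))
            sv <- sv[keep_ev[base_id], , drop = FALSE]
          }
          if (nrow(sv) > 0) {
            info <- ifelse(sv$svtype == "BND",
                           sprintf("SVTYPE=BND;MATEID=%s_%s",
                                   sub("_[12]$", "", sv$event_id),
                                   ifelse(grepl("_1$", sv$event_id), "2",
                                          "1")),
                           ifelse(sv$svtype == "DEL",
                                  sprintf("END=%d;SVTYPE=DEL;SVLEN=%d",
                                          sv$end, sv$svlen),
                                  sprintf("END=%d;SVTYPE=INV", sv$end)))
            meta[[length(meta) + 1L]] <- data.frame(
              chrom = sv$chrom, pos = sv$pos, id = sv$event_id,
              ref = sv$ref, alt = sv$alt, info = info,
              zygosity = sv$zygosity, stringsAsFactors = FALSE)
          }
        }
        # injected shared false positives (small-variant caller only)
        if (!is.null(fp_sites) && caller == "snv_indel_caller") {
          hit <- vapply(strsplit(fp_sites$samples, ","), function(ss)
            pl %in% ss, logical(1))
          if (any(hit)) {
            f <- fp_sites[hit, , drop = FALSE]
            meta[[length(meta) + 1L]] <- data.frame(
              chrom = f$chrom, pos = f$pos, id = ".", ref = f$ref,
              alt = f$alt, info = ".", zygosity = "het",
              stringsAsFactors = FALSE)
          }
        }
        path <- file.path(dir, sprintf("%s.%s.vcf", pl, caller))
        if (length(meta) > 0) {
          m <- do.call(rbind, meta)
          m <- m[order(m$chrom, m$pos), , drop = FALSE]
          rd <- sample_reads(nrow(m), m$zygosity, noise)
          lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tAD:DP\t%d,%d:%d",
                           m$chrom, m$pos, m$id, m$ref, m$alt, m$info,
                           rd$depth - rd$alt, rd$alt, rd$depth)
        }
        writeLines(c(vcf_header(truth$genome, pl), lines), path)
        manifest[[length(manifest) + 1L]] <- data.frame(
          sample = pl, caller = caller, path = path,
          stringsAsFactors = FALSE)
      }
    }
    list(manifest = do.call(rbind, manifest),
         fp_log = if (length(fp_rows)) fp_rows else
           data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      samples = character(), stringsAsFactors = FALSE))
  })
}

#' Simulate a binomial survival assay from a survival curve
#'
#' @param curve a [survival_curve()].
#' @param doses doses in Gy.
#' @param n_per_replicate seedlings per replicate (default 30).
#' @param replicates replicates per dose (default 3).
#' @param seed RNG seed.
#' @return a dose-response data frame (`dose`, `survivors`, `total`,
#'   `replicate`).
#' @export
simulate_survival <- function(curve, doses, n_per_replicate = 30L,
                              replicates = 3L, seed = NULL) {
  stopifnot(inherits(curve, "survival_curve"))
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates), dose = doses)
    p <- survival_fraction(grid$dose, curve)
    data.frame(dose = grid$dose,
               survivors = rbinom(nrow(grid), n_per_replicate, p),
               total = n_per_replicate, replicate = grid$replicate)
  })
}
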