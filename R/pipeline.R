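# Orchestration: a run configuration, the end-to-end harmonization chain,
# per-stage commands, and a command-line entry point with a one-shot demo.

#' Build a run configuration
#'
#' All thresholds default to the published filtering/classification values.
#' A run is reproducible from the configuration plus its seed; the single
#' seed fans out to independent per-stage streams.
#'
#' @param outdir output directory.
#' @param seed global RNG seed.
#' @param filter a [filter_config()].
#' @param classify a [classify_config()].
#' @param alpha significance level for group comparisons.
#' @param correction multiple-comparison method for exact tests.
#' @param profiles treatment profiles (default [default_profiles()]).
#' @param n_plants plants per treatment group.
#' @param genome_length,genome_gc,genome_chroms synthetic genome settings.
#' @param noise an [emission_noise()].
#' @return a `run_config` list.
#' @export
run_config <- function(outdir = ".", seed = 1L,
                       filter = filter_config(),
                       classify = classify_config(),
                       alpha = 0.05, correction = "holm",
                       profiles = default_profiles(), n_plants = 12L,
                       genome_length = 2e6, genome_gc = 0.36,
                       genome_chroms = 2L, noise = emission_noise()) {
  structure(list(outdir = outdir, seed = as.integer(seed), filter = filter,
                 classify = classify, alpha = alpha, correction = correction,
                 profiles = profiles, n_plants = as.integer(n_plants),
                 genome_length = genome_length, genome_gc = genome_gc,
                 genome_chroms = as.integer(genome_chroms), noise = noise),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized keys mirror the [run_config()] arguments (scalar fields plus
#' nested `filter`, `classify`, `noise` blocks). Unknown keys are an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("outdir", "seed", "alpha", "correction", "n_plants",
             "genome_length", "genome_gc", "genome_chroms", "filter",
             "classify", "noise")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- run_config()
  for (k in intersect(names(raw), c("outdir", "seed", "alpha", "correction",
                                    "n_plants", "genome_length", "genome_gc",
                                    "genome_chroms")))
    cfg[[k]] <- raw[[k]]
  if (!is.null(raw$filter))
    cfg$filter <- do.call(filter_config, raw$filter)
  if (!is.null(raw$classify))
    cfg$classify <- do.call(classify_config, raw$classify)
  if (!is.null(raw$noise))
    cfg$noise <- do.call(emission_noise, raw$noise)
  cfg
}

#' Harmonize a set of caller VCFs into a classified catalog
#'
#' Reads every (sample, caller, path) row of the manifest, pools the
#' records, applies the recurrence/AF/zygosity filters, and classifies the
#' retained records into the eight-category catalog.
#'
#' @param manifest data frame with columns `sample`, `caller`, `path`.
#' @param filter a [filter_config()].
#' @param classify a [classify_config()].
#' @return list: `catalog` (classified `mutation_catalog`), `records`
#'   (raw record count), `recurrence_log`, `exclusions`, `counts`
#'   (per-stage in/out tallies).
#' @export
harmonize_vcfs <- function(manifest, filter = filter_config(),
                           classify = classify_config()) {
  recs <- do.call(bind_records, lapply(seq_len(nrow(manifest)), function(i)
    read_caller_vcf(manifest$path[i], manifest$caller[i],
                    manifest$sample[i])))
  flt <- apply_site_filters(recs, filter)
  catalog <- classify_records(flt$retained, classify,
                              sv_tolerance = filter$sv_endpoint_tolerance)
  list(catalog = catalog, records = nrow(recs),
       recurrence_log = flt$recurrence_log, exclusions = flt$exclusions,
       counts = c(records_in = nrow(recs),
                  records_retained = nrow(flt$retained),
                  records_excluded = nrow(flt$exclusions),
                  events_out = nrow(catalog)))
}

#' Compare a harmonized catalog against a synthetic truth
#'
#' Events match when sample, chromosome, span, category, net length and
#' zygosity all agree (SV events match on sample/chromosome/kind/junctions).
#'
#' @param catalog a classified `mutation_catalog`.
#' @param truth a `synthetic_truth`.
#' @return list: `precision`, `recall`, `n_truth`, `n_called`, `n_matched`.
#' @export
recovery_stats <- function(catalog, truth) {
  tc <- truth_catalog(truth)
  key <- function(df) paste(df$sample, df$chrom, df$start, df$end,
                            df$category, df$net_length, df$zygosity,
                            df$sv_kind, df$components)
  tk <- key(tc); ck <- key(catalog)
  n_matched <- length(intersect(tk, ck))
  list(precision = if (nrow(catalog) == 0) NA_real_ else
    n_matched / nrow(catalog),
    recall = if (nrow(tc) == 0) NA_real_ else n_matched / nrow(tc),
    n_truth = nrow(tc), n_called = nrow(catalog), n_matched = n_matched)
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates a genome and per-treatment ground-truth catalogs, emits caller
#' VCFs, harmonizes them back through the filters and classifier, and
#' writes catalogs plus a stats report (markdown + JSON) under `outdir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the per-treatment catalogs, recovery
#'   statistics and the report list.
#' @export
run_demo <- function(config = run_config(), quiet = FALSE) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  genome <- make_genome(config$genome_length, config$genome_gc,
                        seed = substream(config$seed, 1),
                        n_chrom = config$genome_chroms)
  write_fasta(genome, file.path(config$outdir, "genome.fa"))
  results <- list()
  report <- list(seed = config$seed, treatments = list())
  k <- 1L
  for (nm in names(config$profiles)) {
    k <- k + 1L
    prof <- config$profiles[[nm]]
    say("simulating treatment ", nm)
    truth <- simulate_catalog(prof, config$n_plants, genome,
                              seed = substream(config$seed, 10 * k))
    em <- emit_caller_outputs(truth, file.path(config$outdir, "vcf", nm),
                              noise = config$noise,
                              seed = substream(config$seed, 10 * k + 1))
    say("harmonizing ", nrow(em$manifest), " VCFs")
    h <- harmonize_vcfs(em$manifest, config$filter, config$classify)
    write_catalog(h$catalog,
                  file.path(config$outdir, paste0(nm, ".catalog.tsv")))
    rec <- recovery_stats(h$catalog, truth)
    zyg <- table(factor(h$catalog$zygosity, levels = c("hom", "het")))
    rs <- rearrangement_summary(h$catalog, plants = truth$plants)
    report$treatments[[nm]] <- list(
      n_events = nrow(h$catalog),
      mutation_frequency = mutation_frequency(nrow(h$catalog) /
                                                config$n_plants,
                                              genome$total_length),
      precision = rec$precision, recall = rec$recall,
      hom = unname(zyg[["hom"]]), het = unname(zyg[["het"]]),
      percent_plants_with_rearrangement =
        rs$percent_plants_with_rearrangement,
      mean_rearrangements_per_plant = rs$mean_events_per_plant,
      stage_counts = as.list(h$counts))
    results[[nm]] <- list(truth = truth, catalog = h$catalog, recovery = rec)
  }
  report_paths <- write_report(report, config$outdir)
  say("report written to ", report_paths$json)
  invisible(list(results = results, report = report, genome = genome))
}

write_report <- function(report, outdir) {
  json <- file.path(outdir, "report.json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  md <- file.path(outdir, "report.md")
  lines <- c("# radmut synthetic pipeline report", "",
             sprintf("Seed: %d", report$seed), "",
             "| treatment | events | MF/plant/bp | precision | recall | hom | het | % plants w/ rearr. | rearr./plant |",
             "|---|---|---|---|---|---|---|---|---|")
  for (nm in names(report$treatments)) {
    t <- report$treatments[[nm]]
    lines <- c(lines, sprintf(
      "| %s | %d | %.3g | %.3f | %.3f | %d | %d | %d%% | %.1f |",
      nm, t$n_events, t$mutation_frequency, t$precision, t$recall,
      t$hom, t$het, t$percent_plants_with_rearrangement,
      t$mean_rearrangements_per_plant))
  }
  writeLines(lines, md)
  list(json = json, md = md)
}

#' Command-line entry point
#'
#' Subcommands: `demo` (full synthetic chain), `simulate`, `filter`,
#' `classify`, `stats`, `survival`, `report`. Exit codes: 0 success, 2
#' configuration error, 3 data error.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return integer exit code, invisibly.
#' @export
radmut_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: radmut <command> [--config FILE] [--seed N] [--outdir DIR]",
    "commands: demo | simulate | filter | classify | stats | survival",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[[1]]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--outdir", type = "character", default = "."),
      optparse::make_option("--input", type = "character", default = NULL))),
    args = args[-1])
  code <- tryCatch({
    cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
    else run_config()
    cfg$outdir <- opts$outdir
    cfg$seed <- opts$seed
    switch(cmd,
      demo = { run_demo(cfg); 0L },
      simulate = {
        genome <- make_genome(cfg$genome_length, cfg$genome_gc,
                              seed = substream(cfg$seed, 1),
                              n_chrom = cfg$genome_chroms)
        dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
        write_fasta(genome, file.path(cfg$outdir, "genome.fa"))
        for (nm in names(cfg$profiles)) {
          truth <- simulate_catalog(cfg$profiles[[nm]], cfg$n_plants, genome,
                                    seed = substream(cfg$seed, 100))
          emit_caller_outputs(truth, file.path(cfg$outdir, "vcf", nm),
                              noise = cfg$noise,
                              seed = substream(cfg$seed, 101))
          write_catalog(truth_catalog(truth),
                        file.path(cfg$outdir, paste0(nm, ".truth.tsv")))
        }
        0L
      },
      survival = {
        if (is.null(opts$input)) stop("survival requires --input CSV")
        d <- read_dose_response(opts$input)
        fit <- fit_survival(d)
        out <- file.path(cfg$outdir, "survival_fit.json")
        jsonlite::write_json(list(D0 = fit$D0, m = fit$m, Dq = fit$Dq,
                                  rss = fit$rss),
                             out, auto_unbox = TRUE, digits = NA)
        message("D0 = ", signif(fit$D0, 4), " Gy, m = ", signif(fit$m, 4),
                ", Dq = ", signif(fit$Dq, 4), " Gy -> ", out)
        0L
      },
      filter = ,
      classify = ,
      stats = {
        if (is.null(opts$input)) stop(cmd, " requires --input")
        manifest <- utils::read.delim(opts$input, stringsAsFactors = FALSE)
        h <- harmonize_vcfs(manifest, cfg$filter, cfg$classify)
        dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
        write_catalog(h$catalog, file.path(cfg$outdir, "catalog.tsv"))
        utils::write.table(h$exclusions,
                           file.path(cfg$outdir, "exclusions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        message(paste(names(h$counts), h$counts, sep = "=", collapse = " "))
        0L
      },
      { message("unknown command: ", cmd, "\n", usage); 2L })
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config", conditionMessage(e), ignore.case = TRUE)) 2L else 3L
  })
  invisible(code)
}
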