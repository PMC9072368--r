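## End-to-end orchestration: simulate -> call -> classify -> profile
## (-> conserve) from a single validated configuration.

#' Default pipeline configuration
#'
#' Returns the full configuration schema with defaults; unknown keys in
#' a user configuration are rejected by [validateRunConfig()].
#'
#' @return Nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    out_dir = "m5c_run",
    stages = list(simulate = TRUE, call = TRUE, classify = TRUE,
                  metagene = TRUE, conserve = FALSE),
    simulate = list(n_genes = 50L, n_sites = 100L, type_mix = 0.2,
                    utr5 = 150L, cds = 1350L, utr3 = 500L,
                    coverage_mean = 60, conversion_rate = 0.995,
                    bad_read_fraction = 0.02, read_len = 100L,
                    level_lo = 0.2, level_hi = 0.8),
    caller = list(min_coverage = 20L, min_level = 0.1,
                  min_variant_reads = 3L, min_base_qual = 30L,
                  c_cutoff = 3L, min_signal_ratio = 0.9,
                  p_threshold = 0.001, combined_p_threshold = 0.001,
                  single_rep_min_variant = 5L,
                  resistant_gene_max_nonconversion = 0.05,
                  min_gene_obs = 50L),
    classify = list(registration = "downstream_ucna"),
    metagene = list(n_utr5 = 10L),
    conserve = list(sub_rate = 0.05, retention_logit = 0,
                    min_pair_coverage = 10L))
}

#' Validate a pipeline configuration
#'
#' Checks the configuration (list or YAML path) against the schema of
#' [defaultRunConfig()]; unknown keys anywhere are rejected before any
#' stage runs. Missing keys inherit defaults.
#'
#' @param config Nested list or path to a YAML file.
#' @return The merged, validated configuration.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- defaultRunConfig()
  check <- function(user, def, path) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0L) {
      stop("unknown configuration key(s): ",
           paste(paste0(path, unknown), collapse = ", "), call. = FALSE)
    }
    for (k in names(user)) {
      if (is.list(def[[k]])) {
        if (!is.list(user[[k]])) {
          stop("configuration section expected at ", path, k,
               call. = FALSE)
        }
        def[[k]] <- check(user[[k]], def[[k]], paste0(path, k, "."))
      } else {
        def[[k]] <- user[[k]]
      }
    }
    def
  }
  check(config, defaults, "")
}

config_hash <- function(config) {
  config$out_dir <- NULL  # output location does not change the science
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

write_stage_table <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m5Cquant config_hash=%s seed=%d", hash,
                     as.integer(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline end to end
#'
#' Runs the enabled stages in dependency order (simulate, call,
#' classify, metagene, conserve), writes every stage table under
#' `out_dir` with a config-hash/seed header comment, and records a
#' manifest with md5 checksums. Re-running with an unchanged
#' configuration is a no-op unless `force = TRUE`.
#'
#' @param config Configuration list or YAML path (see
#'   [defaultRunConfig()]).
#' @param force Recompute even when an identical run is already
#'   present.
#' @return Invisibly, the manifest `data.frame` (file, md5), with the
#'   in-memory stage results attached as attribute `results`.
#' @export
runPipeline <- function(config = defaultRunConfig(), force = FALSE) {
  cfg <- validateRunConfig(config)
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.tsv")
  if (!force && file.exists(manifest_path)) {
    old <- read.table(manifest_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    if (identical(attr_hash <- unique(old$config_hash), hash) &&
        all(file.exists(file.path(cfg$out_dir, old$file)))) {
      message("runPipeline: outputs up to date; use force = TRUE to rerun")
      return(invisible(old))
    }
  }
  results <- list()
  files <- character()

  message("stage: simulate")
  sim_cfg <- cfg$simulate
  tx0 <- makeTranscriptome(sim_cfg$n_genes,
                           list(utr5 = sim_cfg$utr5, cds = sim_cfg$cds,
                                utr3 = sim_cfg$utr3),
                           seed = child_seed(cfg$seed, "transcriptome"))
  planted <- plantTruth(tx0, sim_cfg$n_sites, sim_cfg$type_mix,
                        level_dist = function(n) {
                          runif(n, sim_cfg$level_lo, sim_cfg$level_hi)
                        },
                        seed = child_seed(cfg$seed, "truth"))
  tx <- planted$transcriptome
  mk_reads <- function(tag) {
    simulateReads(tx, planted$truth, simulationConfig(
      coverage_mean = sim_cfg$coverage_mean,
      conversion_rate = sim_cfg$conversion_rate,
      bad_read_fraction = sim_cfg$bad_read_fraction,
      read_len = sim_cfg$read_len,
      seed = child_seed(cfg$seed, tag)))
  }
  rep1 <- mk_reads("rep1"); rep2 <- mk_reads("rep2")
  results$transcriptome <- tx
  results$truth <- planted$truth
  files <- c(files, "truth.tsv")
  write_stage_table(planted$truth, file.path(cfg$out_dir, "truth.tsv"),
                    hash, cfg$seed)

  if (isTRUE(cfg$stages$call)) {
    message("stage: call")
    caller_cfg <- do.call(callerConfig, cfg$caller)
    calls <- callSites(rep1, rep2, tx, caller_cfg)
    results$calls <- calls
    files <- c(files, "sites.tsv")
    df <- sites(calls)
    df$pos <- df$pos + 1L  # 1-based in exports
    write_stage_table(df, file.path(cfg$out_dir, "sites.tsv"), hash,
                      cfg$seed)
  }

  if (isTRUE(cfg$stages$classify) && !is.null(results$calls)) {
    message("stage: classify")
    site_df <- sites(results$calls)
    cls <- classifySites(siteContexts(tx, site_df),
                         registration = cfg$classify$registration)
    results$classified <- cls
    files <- c(files, "sites_typed.tsv")
    write_stage_table(cls, file.path(cfg$out_dir, "sites_typed.tsv"),
                      hash, cfg$seed)
  }

  if (isTRUE(cfg$stages$metagene) && !is.null(results$calls)) {
    message("stage: metagene")
    layout <- deriveLayout(tx, cfg$metagene$n_utr5)
    pile <- pileupFromReads(rep1)
    background <- pile[pile$cov_hq >= cfg$caller$min_coverage,
                       c("transcript_id", "pos")]
    prof <- densityProfile(sites(results$calls), background, tx, layout)
    gc <- gcProfile(tx, layout)
    prof$gc <- gc$gc
    results$profile <- prof
    files <- c(files, "metagene.tsv")
    write_stage_table(prof, file.path(cfg$out_dir, "metagene.tsv"), hash,
                      cfg$seed)
  }

  if (isTRUE(cfg$stages$conserve)) {
    message("stage: conserve")
    pair <- makeSpeciesPair(
      tx, planted$truth, sub_rate = cfg$conserve$sub_rate,
      glm_coefs = c("(Intercept)" = cfg$conserve$retention_logit),
      seed = child_seed(cfg$seed, "pair"))
    st <- pair$site_truth
    sa <- data.frame(transcript_id = st$transcript_id, pos = st$position,
                     level = st$true_level, coverage = 50L)
    sb <- data.frame(transcript_id = st$transcript_id, pos = st$position,
                     level = ifelse(st$methylated_b, st$true_level, 0),
                     coverage = 50L)
    site_map <- pair$ortholog_map[
      paste(pair$ortholog_map$tidA, pair$ortholog_map$posA) %in%
        paste(st$transcript_id, st$position), ]
    calls <- pairSites(sa, sb, site_map,
                       min_pair_coverage = cfg$conserve$min_pair_coverage)
    summ <- conservationSummary(calls, types = st$planted_type)
    results$conservation <- list(calls = calls, summary = summ)
    files <- c(files, "conservation.tsv")
    write_stage_table(summ, file.path(cfg$out_dir, "conservation.tsv"),
                      hash, cfg$seed)
  }

  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(
                           file.path(cfg$out_dir, files))),
                         config_hash = hash, seed = cfg$seed,
                         stringsAsFactors = FALSE)
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  attr(manifest, "results") <- results
  invisible(manifest)
}
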