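#' Read / write FASTA sequence sets
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

pipeline_stage_names <- c("simulate", "tfbr", "share", "decay", "motif",
                          "cluster", "coevolve", "ancestry", "knockout")

#' Default demo pipeline configuration
#'
#' A pure-simulation end-to-end run at desk scale.  Every threshold of
#' every stage is surfaced here with its package default.
#'
#' @param outdir output directory.
#' @param seed integer master seed.
#' @return nested configuration list accepted by [run_pipeline].
#' @export
default_pipeline_config <- function(outdir = "tfbindevo_run",
                                    seed = 1L) {
  list(outdir = outdir, seed = seed, strict = TRUE,
       simulate = list(n_loci = 2000L, loss_rate = 0.12,
                       gain_rate = 0),
       tfbr = list(min_overlap_bp = 1L),
       share = list(min_overlap_bp = 1L,
                    partners = c("AJ", "CAST", "SPRET", "CAROLI",
                                 "RAT")),
       decay = list(exclude = "AJ", intercept = "free"),
       motif = list(window = 150L, min_score_frac = 0.6,
                    partner = "CAROLI", pwm = NULL),
       cluster = list(window = 300L),
       coevolve = list(partner = "SPRET"),
       ancestry = list(tau = 0.585, n_perm = 99L),
       knockout = list(deleted_tf = "HNF4A", min_overlap_bp = 1L))
}

check_keys <- function(given, known, where, strict) {
  extra <- setdiff(names(given), known)
  if (length(extra)) {
    msg <- paste0("unknown ", where, " key(s): ",
                  paste(extra, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
}

# canonical JSON of a config (keys sorted recursively) and its md5 hash,
# stable under key reordering
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes, in dependency order: synthetic-data generation, TFBR
#' definition from replicates, cross-species sharing, turnover-decay
#' fitting, motif-SNV analysis, cluster categorization, co-evolution,
#' ancestral-trajectory analysis, and knockout retention.  Each stage
#' writes its outputs under the configured output directory; a manifest
#' (config hash, seed, per-stage outputs, row counts and wall-clock) is
#' written last.  A failure aborts with a stage-named error.  The run is
#' fully deterministic under a fixed seed.
#'
#' @param config a configuration list (see [default_pipeline_config]) or
#'   the path of a YAML file holding one.
#' @return the manifest, invisibly (list of class `run_manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  strict <- !isFALSE(config$strict)
  check_keys(config, names(defaults), "config", strict)
  for (st in intersect(names(config), pipeline_stage_names))
    check_keys(config[[st]], names(defaults[[st]]),
               paste0(st, " stage"), strict)
  cfg_full <- utils::modifyList(defaults, config)
  outdir <- cfg_full$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(config_hash = config_hash(cfg_full),
                   seed = cfg_full$seed,
                   tool = paste0("tfbindevo ",
                                 as.character(utils::packageVersion(
                                   "tfbindevo"))),
                   stages = list())
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      name = name, outputs = res$outputs, rows = res$rows,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(NULL)
  }
  rel <- function(...) file.path(outdir, ...)

  run_stage("simulate", function() {
    sc <- cfg_full$simulate
    cfg <- sim_config(n_loci = sc$n_loci, loss_rate = sc$loss_rate,
                      seed = cfg_full$seed)
    state$cfg <- cfg
    state$tree <- build_study_phylogeny()
    state$turnover <- simulate_turnover(cfg, gain_rate = sc$gain_rate)
    state$intens <- simulate_intensities(state$turnover, cfg)
    state$cob <- simulate_cobinding(
      cfg, partner_species = cfg_full$coevolve$partner)
    state$pwm <- if (is.null(cfg_full$motif$pwm))
      read_pfm(system.file("extdata", "cebpa_synthetic.pfm",
                           package = "tfbindevo"))
    else read_pfm(cfg_full$motif$pwm)
    outs <- character()
    ape::write.tree(state$tree, rel("tree.nwk"))
    outs <- c(outs, "tree.nwk")
    for (sp in names(state$turnover$peaks)) {
      f <- sprintf("turnover_%s.narrowPeak", sp)
      write_peaks(state$turnover$peaks[[sp]], rel(f))
      outs <- c(outs, f)
    }
    for (sp in names(state$turnover$maps)) {
      f <- sprintf("map_C57BL6J_%s.tsv", sp)
      write_orthology_map(state$turnover$maps[[sp]], rel(f))
      outs <- c(outs, f)
    }
    anchor <- state$intens$peaks$C57BL6J
    for (cond in c("rep1", "rep2", "pooled")) {
      f <- sprintf("anchor_%s.narrowPeak", cond)
      write_peaks(anchor[[cond]], rel(f))
      outs <- c(outs, f)
    }
    utils::write.table(state$turnover$truth, rel("truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, "truth.tsv")
    list(outputs = outs, rows = nrow(state$turnover$truth))
  })

  run_stage("tfbr", function() {
    anchor <- state$intens$peaks$C57BL6J
    state$tfbrs <- define_tfbrs(anchor$rep1, anchor$rep2,
                                anchor$pooled,
                                cfg_full$tfbr$min_overlap_bp)
    write_peaks(state$tfbrs, rel("tfbr_C57BL6J.narrowPeak"))
    list(outputs = "tfbr_C57BL6J.narrowPeak", rows = nrow(state$tfbrs))
  })

  run_stage("share", function() {
    partners <- cfg_full$share$partners
    anchor <- state$turnover$peaks$C57BL6J
    fr <- lapply(partners, function(sp) {
      calls <- call_shared(anchor, state$turnover$peaks[[sp]],
                           state$turnover$maps[[sp]],
                           cfg_full$share$min_overlap_bp)
      write_sharing_calls(calls, rel(sprintf("share_%s.tsv", sp)))
      data.frame(partner = sp,
                 t = state$cfg$divergence_times[[sp]],
                 n_shared = sum(calls$status == "shared"),
                 n_alignable = sum(calls$status != "unalignable"),
                 fraction = mean(calls$status[calls$status !=
                   "unalignable"] == "shared"),
                 stringsAsFactors = FALSE)
    })
    state$sharing <- do.call(rbind, fr)
    utils::write.table(state$sharing, rel("sharing.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(outputs = c(sprintf("share_%s.tsv", partners), "sharing.tsv"),
         rows = nrow(state$sharing))
  })

  run_stage("decay", function() {
    pts <- state$sharing[!state$sharing$partner %in%
                           cfg_full$decay$exclude, ]
    fit <- fit_decay(data.frame(t = pts$t, fraction = pts$fraction),
                     intercept = cfg_full$decay$intercept)
    jsonlite::write_json(unclass(fit), rel("decay_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    state$decay <- fit
    list(outputs = "decay_fit.json", rows = nrow(pts))
  })

  run_stage("motif", function() {
    sp <- cfg_full$motif$partner
    shared <- state$turnover$truth[[paste0("present_", sp)]]
    status <- data.frame(locus_id = state$turnover$truth$locus_id,
                         shared = shared, stringsAsFactors = FALSE)
    ms <- simulate_motifs(status, state$pwm, state$cfg,
                          window = cfg_full$motif$window)
    write_fasta(ms$anchor, rel("seq_anchor.fa"))
    write_fasta(ms$partner, rel(sprintf("seq_%s.fa", sp)))
    min_score <- cfg_full$motif$min_score_frac *
      pwm_max_score(state$pwm)
    res <- lapply(seq_along(ms$anchor), function(i) {
      r <- summit_motif_snv(ms$anchor[[i]], ms$partner[[i]],
                            state$pwm, min_score)
      if (is.null(r$hit))
        return(data.frame(locus_id = names(ms$anchor)[i],
                          hit_start = NA_integer_,
                          hit_end = NA_integer_,
                          strand = NA_character_, score = NA_real_,
                          n_snv = 0L, delta_score = NA_real_,
                          stringsAsFactors = FALSE))
      data.frame(locus_id = names(ms$anchor)[i],
                 hit_start = r$hit$start, hit_end = r$hit$end,
                 strand = r$hit$strand, score = r$hit$score,
                 n_snv = nrow(r$snvs),
                 delta_score = sum(r$snvs$delta_bits),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    utils::write.table(res, rel("motif_snv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
    tab <- table(shared = factor(status$shared, c(TRUE, FALSE)),
                 snv = factor(res$n_snv > 0, c(TRUE, FALSE)))
    ct <- snv_contingency(unclass(tab))
    jsonlite::write_json(list(table = unclass(tab),
                              odds_ratio = ct$odds_ratio,
                              p_value = ct$p_value,
                              log_p = ct$log_p),
                         rel("motif_contingency.json"),
                         auto_unbox = TRUE, digits = NA)
    list(outputs = c("seq_anchor.fa", sprintf("seq_%s.fa", sp),
                     "motif_snv.tsv", "motif_contingency.json"),
         rows = nrow(res))
  })

  run_stage("cluster", function() {
    state$clusters <- categorize_clusters(state$cob$peaks$C57BL6J,
                                          cfg_full$cluster$window)
    write_cluster_calls(state$clusters, rel("clusters.tsv"))
    comp <- cluster_composition(state$clusters)
    jsonlite::write_json(as.list(comp), rel("cluster_composition.json"),
                         auto_unbox = TRUE, digits = NA)
    list(outputs = c("clusters.tsv", "cluster_composition.json"),
         rows = nrow(state$clusters$clusters))
  })

  run_stage("coevolve", function() {
    sp <- cfg_full$coevolve$partner
    res <- coevolution(state$clusters, state$cob$peaks[[sp]],
                       state$cob$maps[[sp]])
    utils::write.table(as.data.frame(res), rel("coevolution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(outputs = "coevolution.tsv", rows = nrow(res))
  })

  run_stage("ancestry", function() {
    pres <- as.matrix(state$turnover$truth[, paste0("present_",
                                                    MOUSE_SPECIES)])
    deep <- rowSums(pres) == length(MOUSE_SPECIES)
    X <- state$intens$log2[deep, MOUSE_SPECIES, drop = FALSE]
    X <- sweep(X, 2L, apply(X, 2L, stats::median), "-")
    mt <- mouse_clade(state$tree)
    prof <- ancestral_profiles(X, mt, cfg_full$ancestry$tau)
    utils::write.table(prof, rel("ancestral_profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    null <- randomization_null(X, mt, cfg_full$ancestry$tau,
                               cfg_full$ancestry$n_perm,
                               seed = cfg_full$seed)
    jsonlite::write_json(list(observed = as.list(null$observed),
                              p = as.list(null$p),
                              n_perm = null$n_perm),
                         rel("ancestry_null.json"), auto_unbox = TRUE,
                         digits = NA)
    list(outputs = c("ancestral_profiles.tsv", "ancestry_null.json"),
         rows = nrow(prof))
  })

  run_stage("knockout", function() {
    del <- cfg_full$knockout$deleted_tf
    wt <- state$cob$peaks$C57BL6J
    ko <- simulate_knockout(wt, state$cob$members, del, state$cfg)
    for (tf in names(ko))
      write_peaks(ko[[tf]], rel(sprintf("ko_%s_%s.narrowPeak", del,
                                        tf)))
    rep <- retention_by_class(state$clusters, ko, del,
                              cfg_full$knockout$min_overlap_bp)
    utils::write.table(rep$per_member, rel("ko_retention.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(deleted_tf = del, self_retention = rep$self_retention,
           contrasts = rep$contrasts),
      rel("ko_contrasts.json"), auto_unbox = TRUE, digits = NA)
    list(outputs = c(sprintf("ko_%s_%s.narrowPeak", del, names(ko)),
                     "ko_retention.tsv", "ko_contrasts.json"),
         rows = nrow(rep$per_member))
  })

  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), rel("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", x$tool, "| seed", x$seed, "| config",
      x$config_hash, "\n")
  for (st in x$stages)
    cat(sprintf("  %-9s %5s rows  %7.2fs  %d file(s)\n", st$name,
                st$rows, st$seconds, length(st$outputs)))
  invisible(x)
}
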