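#' Metabolite sets matching the synthetic cohort
#'
#' A small synthetic pathway collection over the metabolite ids produced by
#' [simulate_tissue_cohort()] under a given configuration: the bile-acid
#' block, one set per trajectory archetype, the subtype signature blocks,
#' and two background sets. Useful as the GMT input of [enrich()] when no
#' user collection is supplied.
#'
#' @param config A [sim_config()] object (defaults used when omitted).
#' @return Named list of metabolite-id sets with a `description` attribute.
#' @export
synthetic_pathways <- function(config = sim_config()) {
  arch <- config$trajectory_archetypes
  sets <- list()
  desc <- character(0)
  for (a in arch) {
    id <- paste0("SYN_", toupper(a$label))
    sets[[id]] <- sprintf("m_%s_%02d", a$label, seq_len(a$n))
    desc[id] <- paste0("synthetic trajectory module: ", a$label)
  }
  n_sig <- as.integer(config$subtype_signature[[1]])
  for (s in seq_len(max(config$n_subtypes - 1L, 0L))) {
    id <- sprintf("SYN_SIG%d", s)
    sets[[id]] <- sprintf("m_sig%d_%02d", s, seq_len(n_sig))
    desc[id] <- sprintf("synthetic subtype S%d signature module", s)
  }
  sets[["SYN_BILE"]] <- bile_acid_names[seq_len(as.integer(config$subtype_block[[1]]))]
  desc["SYN_BILE"] <- "bile acid module (elevated in the last subtype)"
  bg <- sprintf("m_bg_%03d", seq_len(config$n_background))
  half <- ceiling(length(bg) / 2)
  sets[["SYN_BG_A"]] <- bg[seq_len(half)]
  desc["SYN_BG_A"] <- "background module A (no planted effect)"
  sets[["SYN_BG_B"]] <- bg[(half + 1):length(bg)]
  desc["SYN_BG_B"] <- "background module B (no planted effect)"
  attr(sets, "description") <- desc
  sets
}

#' Assemble and validate a pipeline run configuration
#'
#' One serialized source of truth for a full run: the simulation
#' configuration plus per-stage parameter blocks, all validated before any
#' stage executes.
#'
#' @param sim A [sim_config()] object.
#' @param preprocess List: `threshold`, `baseline`, `qc_mode`.
#' @param diff List: `fdr_cut`, `fc_up`, `fc_down`.
#' @param trajectory List: `c`, `m`, `fdr_cut`, `min_membership`.
#' @param subtype List: `k_range`, `reps`, `p_item`.
#' @param enrichment List: `gmt` (path or `NULL` for the synthetic
#'   collection), `fdr_cut`.
#' @param panels Named list of panels, each
#'   `list(metabolites, negative, positive)`.
#' @param survival List: `bile_quantile`, `minprop`.
#' @param seed Global seed; overrides `sim$seed`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       preprocess = list(threshold = 0.8, baseline = 1000,
                                         qc_mode = "batch"),
                       diff = list(fdr_cut = 0.05, fc_up = 1.25, fc_down = 0.8),
                       trajectory = list(c = 4, m = 2, fdr_cut = 0.1,
                                         min_membership = 0),
                       subtype = list(k_range = 2:6, reps = 1000, p_item = 0.8),
                       enrichment = list(gmt = NULL, fdr_cut = 0.05),
                       panels = default_panels(),
                       survival = list(bile_quantile = 0.4, minprop = 0.1),
                       seed = 1) {
  cfg <- list(sim = sim, preprocess = preprocess, diff = diff,
              trajectory = trajectory, subtype = subtype,
              enrichment = enrichment, panels = panels,
              survival = survival, seed = seed)
  class(cfg) <- "run_config"
  errs <- validate_config(cfg)
  if (length(errs) > 0L) {
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  cfg
}

#' Default plasma biomarker panels
#'
#' The three diagnostic contrasts of this study design, each with its
#' marker set: a four-metabolite panel for benign vs any malignant stage, a
#' cystine/valine panel for benign vs pre-invasive disease, and an
#' asparagine/cystine panel for benign vs AIS.
#'
#' @return Named list of panels (`metabolites`, `negative`, `positive`).
#' @export
default_panels <- function() {
  list(
    benign_vs_AIS_MIA_IAC = list(
      metabolites = c("3-chlorotyrosine", "dodecanoylcarnitine",
                      "glutamate", "phosphocholine"),
      negative = "benign", positive = c("AIS", "MIA", "IAC")),
    benign_vs_AIS_MIA = list(
      metabolites = c("cystine", "valine"),
      negative = "benign", positive = c("AIS", "MIA")),
    benign_vs_AIS = list(
      metabolites = c("asparagine", "cystine"),
      negative = "benign", positive = "AIS")
  )
}

#' Validate a run configuration
#'
#' Checks every stage block before any stage runs; all problems are
#' reported at once.
#'
#' @param cfg A `run_config` (or structurally identical list).
#' @return Character vector of error messages (empty when valid).
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  sim_ok <- tryCatch({ validate_sim_config(cfg$sim); TRUE },
                     error = function(e) { errs <<- c(errs, conditionMessage(e)); FALSE })
  chk(cfg$preprocess$threshold > 0 && cfg$preprocess$threshold <= 1,
      "preprocess$threshold must lie in (0, 1]")
  chk(cfg$preprocess$baseline >= 0, "preprocess$baseline must be >= 0")
  chk(cfg$preprocess$qc_mode %in% c("batch", "sliding"),
      "preprocess$qc_mode must be 'batch' or 'sliding'")
  chk(cfg$diff$fdr_cut > 0 && cfg$diff$fdr_cut <= 1,
      "diff$fdr_cut must lie in (0, 1]")
  chk(cfg$diff$fc_up > 1, "diff$fc_up must exceed 1")
  chk(cfg$diff$fc_down > 0 && cfg$diff$fc_down < 1,
      "diff$fc_down must lie in (0, 1)")
  chk(cfg$trajectory$c >= 2, "trajectory$c must be at least 2")
  chk(cfg$trajectory$m > 1, "trajectory$m (fuzzifier) must exceed 1")
  chk(cfg$trajectory$fdr_cut > 0 && cfg$trajectory$fdr_cut <= 1,
      "trajectory$fdr_cut must lie in (0, 1]")
  chk(all(cfg$subtype$k_range >= 2), "subtype$k_range entries must be >= 2")
  chk(cfg$subtype$reps >= 1, "subtype$reps must be >= 1")
  chk(cfg$subtype$p_item > 0 && cfg$subtype$p_item <= 1,
      "subtype$p_item must lie in (0, 1]")
  chk(cfg$enrichment$fdr_cut > 0 && cfg$enrichment$fdr_cut <= 1,
      "enrichment$fdr_cut must lie in (0, 1]")
  chk(is.null(cfg$enrichment$gmt) || file.exists(cfg$enrichment$gmt),
      "enrichment$gmt path does not exist")
  for (nm in names(cfg$panels)) {
    p <- cfg$panels[[nm]]
    chk(length(p$metabolites) >= 1 && length(p$negative) >= 1 &&
          length(p$positive) >= 1,
        paste0("panel '", nm, "' needs metabolites and two stage groups"))
  }
  chk(cfg$survival$bile_quantile > 0 && cfg$survival$bile_quantile < 1,
      "survival$bile_quantile must lie strictly between 0 and 1")
  chk(cfg$survival$minprop > 0 && cfg$survival$minprop < 0.5,
      "survival$minprop must lie in (0, 0.5)")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed must be a single number")
  errs
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, differential, trajectory, subtype,
#' enrichment, panel, and survival stages in dependency order, writing
#' every stage's tables under `out_dir` and a machine-readable JSON run
#' report (parameters, seeds, output files with md5 hashes and row counts).
#' Rerunning with an identical configuration reproduces identical outputs.
#' A stage failure aborts with the failing stage named and leaves a
#' `FAILED` marker next to the partial outputs.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  errs <- validate_config(config)
  if (length(errs) > 0L) {
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  report <- list(seed = config$seed, stages = list())
  t_all <- Sys.time()
  files <- character(0)
  current_stage <- NA_character_
  record <- function(stage, params, outputs, extra = list()) {
    info <- lapply(outputs, function(f) {
      n <- tryCatch(length(readLines(f, warn = FALSE)) - 1L,
                    error = function(e) NA_integer_)
      list(path = f, md5 = unname(tools::md5sum(f)), rows = n)
    })
    report$stages[[stage]] <<- c(list(parameters = params, outputs = info),
                                 extra)
    files <<- c(files, outputs)
  }
  run_stage <- function(stage, fun) {
    current_stage <<- stage
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste0("FAILED at stage '", stage, "': ",
                        conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
    say(sprintf("[%s] done in %.1fs", stage,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  cfg <- config$sim
  cfg$seed <- config$seed
  env <- new.env()

  run_stage("simulate", function() {
    env$tissue <- simulate_tissue_cohort(cfg)
    env$plasma <- simulate_plasma_cohort(cfg)
    f1 <- file.path(out_dir, "tissue_samples.csv")
    write_results(env$tissue$samples, f1)
    f2 <- file.path(out_dir, "plasma_samples.csv")
    write_results(env$plasma$samples, f2)
    f3 <- file.path(out_dir, "clinical.csv")
    write_results(env$tissue$clinical, f3)
    f4 <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(
      list(tissue = list(trajectory = as.list(env$tissue$truth$trajectory),
                         subtype = as.list(env$tissue$truth$subtype)),
           plasma = list(altered = env$plasma$truth$altered)),
      f4, auto_unbox = TRUE, digits = NA)
    record("simulate", list(seed = config$seed), c(f1, f2, f3, f4))
  })

  run_stage("preprocess", function() {
    pp <- config$preprocess
    env$tis <- preprocess_cohort(env$tissue$peaks, env$tissue$samples,
                                 threshold = pp$threshold,
                                 baseline = pp$baseline,
                                 qc_mode = pp$qc_mode, ratios = TRUE)
    env$pla <- preprocess_cohort(env$plasma$peaks, env$plasma$samples,
                                 threshold = pp$threshold,
                                 baseline = pp$baseline,
                                 qc_mode = pp$qc_mode, ratios = FALSE)
    f1 <- file.path(out_dir, "tissue_filter_report.csv")
    write_results(env$tis$filter_report, f1)
    f2 <- file.path(out_dir, "plasma_filter_report.csv")
    write_results(env$pla$filter_report, f2)
    f3 <- file.path(out_dir, "tissue_ratios.csv")
    write_results(data.frame(metabolite = rownames(env$tis$ratios),
                             env$tis$ratios, check.names = FALSE), f3)
    record("preprocess", pp, c(f1, f2, f3),
           list(n_detected_tissue = nrow(env$tis$filtered),
                n_detected_plasma = nrow(env$pla$filtered)))
  })

  run_stage("differential", function() {
    dd <- config$diff
    sam <- env$tissue$samples
    scaled <- env$tis$scaled
    tables <- list()
    for (st in names(cfg$n_per_stage)) {
      pats <- sam$patient_id[sam$role == "tumor" & sam$stage == st]
      pats <- intersect(pats, sam$patient_id[sam$role == "NAT"])
      tcols <- sam$sample_id[sam$role == "tumor" & sam$patient_id %in% pats]
      ncols <- sam$sample_id[match(paste0("N_", sub("^T_", "", tcols)),
                                   sam$sample_id)]
      tables[[st]] <- call_differential(
        scaled[, tcols, drop = FALSE], scaled[, ncols, drop = FALSE],
        comparison = paste0(st, "_tumor_vs_NAT"), paired = TRUE,
        fdr_cut = dd$fdr_cut, fc_up = dd$fc_up, fc_down = dd$fc_down)
    }
    stage_of <- stats::setNames(sam$stage[sam$role == "tumor"],
                                sam$patient_id[sam$role == "tumor"])
    rat <- env$tis$ratios
    st_pat <- stage_of[colnames(rat)]
    tables$IAC_vs_AAH_AIS <- call_differential(
      rat[, st_pat == "IAC", drop = FALSE],
      rat[, st_pat %in% c("AAH", "AIS"), drop = FALSE],
      comparison = "IAC_vs_AAH_AIS", paired = FALSE,
      fdr_cut = dd$fdr_cut, fc_up = dd$fc_up, fc_down = dd$fc_down)
    tables$IAC_vs_MIA <- call_differential(
      rat[, st_pat == "IAC", drop = FALSE],
      rat[, st_pat == "MIA", drop = FALSE],
      comparison = "IAC_vs_MIA", paired = FALSE,
      fdr_cut = dd$fdr_cut, fc_up = dd$fc_up, fc_down = dd$fc_down)
    env$diff_tables <- tables
    all_tab <- do.call(rbind, tables)
    f1 <- file.path(out_dir, "differential_metabolites.csv")
    write_results(all_tab, f1)
    # plasma stage screen at raw P < 0.1
    psam <- env$plasma$samples
    pcols <- psam$sample_id[psam$role != "QC"]
    env$plasma_kw <- kw_screen(env$pla$scaled[, pcols, drop = FALSE],
                               psam$stage[match(pcols, psam$sample_id)])
    f2 <- file.path(out_dir, "plasma_stage_screen.csv")
    write_results(env$plasma_kw, f2)
    counts <- vapply(tables, function(t) sum(t$direction != "ns"), integer(1))
    record("differential", dd, c(f1, f2),
           list(n_significant = as.list(counts),
                n_plasma_altered_p10 = sum(env$plasma_kw$p < 0.1)))
  })

  run_stage("trajectory", function() {
    tj <- config$trajectory
    sam <- env$tissue$samples
    stage_of <- stats::setNames(sam$stage[sam$role == "tumor"],
                                sam$patient_id[sam$role == "tumor"])
    rat <- env$tis$ratios
    kw <- kw_screen(rat, stage_of[colnames(rat)])
    env$traj_kw <- kw
    sel <- kw$metabolite[kw$fdr < tj$fdr_cut]
    if (length(sel) < tj$c) stop("too few stage-differential metabolites")
    prof <- build_stage_profiles(rat, sam, sel,
                                 stages = names(cfg$n_per_stage))
    std <- standardize_profiles(prof)
    env$fcm <- fuzzy_cmeans(std, c = tj$c, m = tj$m,
                            seed = derive_seed(config$seed, 3L))
    env$traj_assign <- assign_clusters(env$fcm, tj$min_membership)
    f1 <- file.path(out_dir, "trajectory_membership.csv")
    write_results(data.frame(metabolite = rownames(env$fcm$membership),
                             env$fcm$membership,
                             cluster = unname(env$traj_assign),
                             check.names = FALSE), f1)
    f2 <- file.path(out_dir, "trajectory_centers.csv")
    write_results(data.frame(cluster = rownames(env$fcm$centers),
                             env$fcm$centers, check.names = FALSE), f2)
    record("trajectory", tj, c(f1, f2),
           list(n_selected = length(sel)))
  })

  run_stage("subtype", function() {
    sb <- config$subtype
    sam <- env$tissue$samples
    stage_of <- stats::setNames(sam$stage[sam$role == "tumor"],
                                sam$patient_id[sam$role == "tumor"])
    rat <- env$tis$ratios
    iac <- colnames(rat)[stage_of[colnames(rat)] == "IAC"]
    X <- t(log2(rat[, iac, drop = FALSE]))
    X <- scale(X)  # z-score per metabolite
    X <- X[, apply(X, 2, function(v) all(is.finite(v))), drop = FALSE]
    env$cons <- consensus_cluster(X, k_range = sb$k_range, reps = sb$reps,
                                  p_item = sb$p_item,
                                  seed = derive_seed(config$seed, 4L))
    env$kchoice <- select_k(env$cons)
    env$subtypes <- assign_subtypes(env$cons, env$kchoice$chosen_k)
    f1 <- file.path(out_dir, "subtype_assignments.csv")
    write_results(data.frame(patient_id = names(env$subtypes),
                             subtype = paste0("S", env$subtypes)), f1)
    f2 <- file.path(out_dir, "consensus_selection.csv")
    write_results(data.frame(k = env$cons$k_range,
                             area = unname(env$kchoice$area),
                             delta = unname(env$kchoice$delta),
                             within = env$kchoice$within_consensus$mean_within_consensus),
                  f2)
    record("subtype", sb[c("reps", "p_item")], c(f1, f2),
           list(chosen_k = env$kchoice$chosen_k))
  })

  run_stage("enrichment", function() {
    en <- config$enrichment
    sets <- if (is.null(en$gmt)) synthetic_pathways(cfg) else read_gmt(en$gmt)
    rat <- env$tis$ratios
    subt <- env$subtypes
    # subtype-defining metabolites: last subtype vs the others
    k <- env$kchoice$chosen_k
    last <- names(subt)[subt == k]
    rest <- names(subt)[subt != k]
    dt <- call_differential(rat[, last, drop = FALSE],
                            rat[, rest, drop = FALSE],
                            comparison = paste0("S", k, "_vs_rest"),
                            paired = FALSE)
    background <- intersect(rownames(rat), unique(unlist(sets)))
    diff_ids <- intersect(dt$metabolite[dt$direction != "ns"], background)
    lfc <- stats::setNames(dt$log2_fc, dt$metabolite)
    env$enrich_tab <- enrich(diff_ids, background, sets, log2_fc = lfc,
                             fdr_cut = en$fdr_cut)
    f1 <- file.path(out_dir, "pathway_enrichment.csv")
    write_results(env$enrich_tab, f1)
    record("enrichment", en["fdr_cut"], f1,
           list(n_significant_sets = sum(env$enrich_tab$significant)))
  })

  run_stage("panels", function() {
    psam <- env$plasma$samples
    rows <- list()
    env$panel_results <- list()
    for (nm in names(config$panels)) {
      p <- config$panels[[nm]]
      ev <- evaluate_panel(env$pla$scaled, p$metabolites, psam,
                           list(negative = p$negative, positive = p$positive))
      env$panel_results[[nm]] <- ev
      rows[[nm]] <- data.frame(panel = nm,
                               metabolites = paste(p$metabolites, collapse = "+"),
                               auc = ev$auc,
                               separation = ev$panel$separation)
    }
    f1 <- file.path(out_dir, "panel_aucs.csv")
    write_results(do.call(rbind, c(rows, list(make.row.names = FALSE))), f1)
    record("panels", list(n_panels = length(config$panels)), f1,
           list(aucs = lapply(env$panel_results, function(ev) ev$auc)))
  })

  run_stage("survival", function() {
    sv <- config$survival
    clin <- env$tissue$clinical
    subt <- env$subtypes
    idx <- match(names(subt), clin$patient_id)
    lr_dfs <- logrank_test(clin$dfs_months[idx], clin$dfs_event[idx],
                           paste0("S", subt))
    lr_os <- logrank_test(clin$os_months[idx], clin$os_event[idx],
                          paste0("S", subt))
    # bile-acid level stratification at the configured quantile
    bile <- bile_acid_names[seq_len(as.integer(cfg$subtype_block[[1]]))]
    bile <- intersect(bile, rownames(env$tis$ratios))
    lvl <- colMeans(log2(env$tis$ratios[bile, names(subt), drop = FALSE]))
    qs <- quantile_split(lvl, q = sv$bile_quantile)
    lr_bile <- logrank_test(clin$dfs_months[idx], clin$dfs_event[idx],
                            qs$labels)
    cp <- optimal_cutpoint(lvl, clin$dfs_months[idx], clin$dfs_event[idx],
                           minprop = sv$minprop)
    tab <- data.frame(
      analysis = c("subtype_DFS", "subtype_OS", "bile_quantile_DFS",
                   "bile_cutpoint_DFS"),
      chisq = c(lr_dfs$chisq, lr_os$chisq, lr_bile$chisq, cp$statistic^2),
      df = c(lr_dfs$df, lr_os$df, lr_bile$df, 1),
      p = c(lr_dfs$p.value, lr_os$p.value, lr_bile$p.value,
            cp$p_uncorrected),
      detail = c("", "", sprintf("threshold=%.4g", qs$threshold),
                 sprintf("cutoff=%.4g", cp$cutoff)))
    env$survival_tab <- tab
    f1 <- file.path(out_dir, "survival_tests.csv")
    write_results(tab, f1)
    record("survival", sv, f1,
           list(logrank_p_dfs = lr_dfs$p.value))
  })

  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  report$n_outputs <- length(files)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  say(sprintf("pipeline complete: %d outputs in %s", length(files), out_dir))
  invisible(c(report, list(env = env)))
}
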