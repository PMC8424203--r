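#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()],
#' optionally overridden by a named list or a YAML file.  The default
#' input is a simulated two-site factorial study with a neutral
#' N-addition cell and selective control cells, small enough to run on a
#' laptop in minutes.
#'
#' @param overrides Named list (or path to a YAML file) of values to
#'   override.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return Configuration list.
#' @export
default_config <- function(overrides = NULL, seed = 42) {
  cfg <- list(
    seed = seed,
    out_dir = file.path(tempdir(), "assemblyscope_run"),
    input = list(kind = "simulate", n_per_cell = 6, n_taxa = 400,
                 N = 5000, m = 0.3, sigma = 0.4,
                 regimes = list(site1_control = "homogeneous_selection",
                                site1_n = "neutral",
                                site2_control = "homogeneous_selection",
                                site2_n = "neutral")),
    rarefaction = list(depth = NULL),     # NULL = min sample total
    group_column = "cell",
    null_model = list(n_null = 199),
    nst = list(metric = "bray_curtis", n_null = 199),
    correlogram = list(env = c("pH", "NO3"), n_perm = 199,
                       n_classes = NULL, min_pairs = 30),
    network = list(scan = list(start = 0.5, stop = 0.95, step = 0.01),
                   n_random = 100, group_by = "site"))
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

.stage_seed <- function(seed, stage) {
  .sub_seed(seed, sum(utf8ToInt(stage)))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full assembly-inference pipeline
#'
#' Executes the fixed stage order input -> rarefy -> diversity -> null
#' models (betaNTI, RC_bray, process classification) -> NST -> Sloan
#' neutral fit -> niche breadth -> phylogenetic correlogram -> per-group
#' co-association networks, writing tsv/json outputs under
#' `config$out_dir`.  Deterministic given `config$seed`; optional-stage
#' failures (e.g., a network with too few taxa) are logged and skipped.
#'
#' @param config List from [default_config()] (or a YAML path passed
#'   through it).
#' @return A run report list (also written as `report.json`): per-stage
#'   status, parameters, seeds, warnings, output manifest and wall times.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- default_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list(), outputs = character())
  t_all <- Sys.time()
  warnings_log <- character()
  run_stage <- function(name, fun, optional = FALSE) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        if (!optional) stop("stage ", name, " failed: ",
                            conditionMessage(e), call. = FALSE)
        structure(list(message = conditionMessage(e)),
                  class = "stage_failure")
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    status <- if (inherits(res, "stage_failure")) "failed" else "ok"
    report$stages[[name]] <<- list(
      status = status,
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2),
      error = if (status == "failed") res$message else NULL)
    if (status == "failed") NULL else res
  }
  emit <- function(path) {
    report$outputs <<- c(report$outputs, path)
    path
  }

  # -- input -----------------------------------------------------------
  inp <- run_stage("input", function() {
    ic <- config$input
    if (identical(ic$kind, "simulate")) {
      sim <- simulate_study(n_per_cell = ic$n_per_cell, n_taxa = ic$n_taxa,
                            N = ic$N, regimes = unlist(ic$regimes),
                            m = ic$m, sigma = ic$sigma,
                            seed = .stage_seed(config$seed, "input"))
      list(table = sim$table, tree = sim$tree, metadata = sim$metadata)
    } else {
      tab <- read_count_table(ic$table)
      tr <- read_tree(ic$tree)
      md <- read_sample_metadata(ic$metadata, tab)
      md$sample_id <- rownames(md)
      list(table = tab, tree = tr, metadata = md)
    }
  })
  write_count_table(inp$table, emit(file.path(out_dir, "table_input.tsv")))
  ape::write.tree(inp$tree, emit(file.path(out_dir, "tree.nwk")))
  utils::write.table(inp$metadata,
                     emit(file.path(out_dir, "metadata.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- rarefy ----------------------------------------------------------
  tab <- run_stage("rarefy", function() {
    depth <- config$rarefaction$depth
    totals <- rowSums(inp$table)
    if (is.null(depth)) depth <- min(totals)
    if (depth > max(totals))
      stop("rarefaction depth ", depth,
           " exceeds the largest sample total ", max(totals))
    rarefy(inp$table, depth, seed = .stage_seed(config$seed, "rarefy"))
  })
  mt <- match_tree_table(tab, inp$tree)
  tab <- mt$table; tree <- mt$tree
  meta <- inp$metadata[rownames(tab), , drop = FALSE]
  groups <- stats::setNames(as.character(meta[[config$group_column]]),
                            rownames(tab))
  write_count_table(tab, emit(file.path(out_dir, "table_rarefied.tsv")))

  # -- diversity -------------------------------------------------------
  div <- run_stage("diversity", function() {
    alpha <- alpha_diversity(tab, tree)
    bc <- bray_curtis(tab)
    bm <- beta_mntd(tab, tree)
    list(alpha = alpha, bc = bc, bmntd = bm)
  })
  utils::write.table(div$alpha, emit(file.path(out_dir, "alpha.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pairwise_matrix(div$bc, emit(file.path(out_dir, "beta_bc.tsv")))
  write_pairwise_matrix(div$bmntd,
                        emit(file.path(out_dir, "beta_bmntd.tsv")))

  # -- null models: betaNTI against the study-wide tree (tip shuffle over
  # the full regional pool), RC_bray per group so each sub-community uses
  # its own occupancy/abundance pool --------------------------------------
  subtables <- lapply(split(names(groups), groups), function(ids)
    count_table(unclass(tab)[ids, , drop = FALSE]))
  nulls <- run_stage("null_models", function() {
    sp <- null_ensemble_spec(config$null_model$n_null,
                             seed = .stage_seed(config$seed, "null_models"))
    bnti <- beta_nti(tab, tree, sp)
    lapply(subtables, function(sub) {
      ids <- rownames(sub)
      rc <- raup_crick_bray(sub, sp)
      bnti_sub <- pairwise_matrix(unclass(bnti)[ids, ids], "beta_nti",
                                  diagonal = NA_real_)
      classify_processes(bnti_sub, rc)
    })
  })
  if (!is.null(nulls)) {
    pair_tab <- do.call(rbind, lapply(names(nulls), function(g)
      cbind(group = g, nulls[[g]]$pairs)))
    utils::write.table(pair_tab,
                       emit(file.path(out_dir, "process_pairs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_json(list(per_group = lapply(nulls, function(p)
      list(fractions = as.list(p$fractions),
           stochastic = p$stochastic_fraction,
           n_excluded = p$n_excluded))),
      emit(file.path(out_dir, "processes.json")))
  }

  # -- NST (per group, own pool) --------------------------------------
  nst_res <- run_stage("nst", function() {
    sp <- null_ensemble_spec(config$nst$n_null,
                             seed = .stage_seed(config$seed, "nst"))
    lapply(names(subtables), function(g) {
      sub <- subtables[[g]]
      nst(sub, stats::setNames(rep(g, nrow(sub)), rownames(sub)),
          metric = config$nst$metric, spec = sp)
    })
  }, optional = TRUE)
  if (!is.null(nst_res)) {
    pairs_all <- do.call(rbind, lapply(nst_res, function(r) r$pairwise))
    utils::write.table(pairs_all,
                       emit(file.path(out_dir, "nst_pairs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gn <- unlist(lapply(nst_res, function(r) r$group_nst))
    names(gn) <- vapply(nst_res, function(r) names(r$group_nst), "")
    .write_json(as.list(gn), emit(file.path(out_dir, "nst_groups.json")))
  }

  # -- Sloan neutral model (whole table and per group) -----------------
  sloan <- run_stage("sloan", function() {
    whole <- sloan_fit(tab)
    per_group <- lapply(subtables, function(sub)
      tryCatch(sloan_fit(sub), error = function(e) NULL))
    list(whole = whole, per_group = Filter(Negate(is.null), per_group))
  }, optional = TRUE)
  if (!is.null(sloan)) {
    js <- function(f) list(Nm = f$Nm, m = f$m, N = f$N, R2 = f$R2,
                           detection_limit = f$detection_limit,
                           fraction_inside = f$fraction_inside)
    .write_json(c(js(sloan$whole),
                  list(per_group = lapply(sloan$per_group, js))),
                emit(file.path(out_dir, "sloan_fit.json")))
    utils::write.table(sloan$whole$taxa,
                       emit(file.path(out_dir, "sloan_curve.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- niche breadth ---------------------------------------------------
  nb <- run_stage("niche_breadth", function() {
    whole <- levins_breadth(tab)
    per_group <- vapply(split(names(groups), groups), function(ids)
      levins_breadth(count_table(
        unclass(tab)[ids, colSums(unclass(tab)[ids, , drop = FALSE]) > 0,
                     drop = FALSE]))$Bcom,
      numeric(1))
    list(whole = whole, per_group = per_group)
  }, optional = TRUE)
  if (!is.null(nb)) {
    utils::write.table(nb$whole$per_taxon,
                       emit(file.path(out_dir, "niche_breadth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_json(c(list(Bcom = nb$whole$Bcom), as.list(nb$per_group)),
                emit(file.path(out_dir, "niche_breadth.json")))
  }

  # -- correlogram -----------------------------------------------------
  corr <- run_stage("correlogram", function() {
    phylo_signal_correlogram(
      tab, tree, env = meta[, config$correlogram$env, drop = FALSE],
      n_classes = config$correlogram$n_classes,
      n_perm = config$correlogram$n_perm,
      seed = .stage_seed(config$seed, "correlogram"),
      min_pairs = config$correlogram$min_pairs)
  }, optional = TRUE)
  if (!is.null(corr) && !corr$undefined)
    utils::write.table(corr$classes,
                       emit(file.path(out_dir, "correlogram.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # -- networks per group ---------------------------------------------
  net_groups <- stats::setNames(
    as.character(meta[[config$network$group_by]]), rownames(tab))
  nets <- list()
  for (gname in unique(net_groups)) {
    res <- run_stage(paste0("network_", gname), function() {
      ids <- names(net_groups)[net_groups == gname]
      sub <- unclass(tab)[ids, , drop = FALSE]
      sub <- count_table(sub[, colSums(sub) > 0, drop = FALSE])
      prep <- prepare_nodes(sub)
      cm <- taxon_correlations(prep)
      st <- rmt_threshold(cm, scan = config$network$scan)
      net <- build_network(cm, st$St)
      topo <- topology(net)
      roles <- zi_pi(net)
      rnd <- tryCatch(random_ensemble(net, n = config$network$n_random,
                                      seed = .stage_seed(config$seed,
                                                         gname)),
                      error = function(e) NULL)
      list(net = net, topo = topo, roles = roles, random = rnd)
    }, optional = TRUE)
    if (!is.null(res)) nets[[gname]] <- res
  }
  if (length(nets) > 0) {
    topo_all <- do.call(rbind, lapply(names(nets), function(g) {
      df <- nets[[g]]$topo
      if (!is.null(nets[[g]]$random)) {
        rs <- nets[[g]]$random$summary
        df$random_avg_cc <- rs$formatted[rs$metric == "avg_cc"]
        df$random_gd <- rs$formatted[rs$metric == "gd"]
        df$random_modularity <- rs$formatted[rs$metric == "modularity"]
      }
      cbind(group = g, df)
    }))
    utils::write.table(topo_all,
                       emit(file.path(out_dir, "network_topology.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in names(nets)) {
      el <- igraph::as_edgelist(nets[[g]]$net$graph)
      ew <- data.frame(source = el[, 1], target = el[, 2],
                       weight = igraph::E(nets[[g]]$net$graph)$weight,
                       sign = igraph::E(nets[[g]]$net$graph)$sign)
      utils::write.table(ew,
        emit(file.path(out_dir, paste0("network_", g, "_edges.tsv"))),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(nets[[g]]$roles,
        emit(file.path(out_dir, paste0("network_", g, "_zipi.tsv"))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  report$warnings <- warnings_log
  report$config <- config
  report$total_seconds <- round(as.numeric(
    difftime(Sys.time(), t_all, units = "secs")), 2)
  .write_json(report, file.path(out_dir, "report.json"))
  invisible(report)
}

#' Summarise a pipeline run into figure-analog tables
#'
#' Writes one tidy tsv per analysis block: five-process fractions per
#' group, group NST, and the network topology table; returns them
#' invisibly.  Blocks whose stage output is missing are skipped with a
#' notice.
#'
#' @param out_dir The pipeline output directory.
#' @return Named list of data frames.
#' @export
summarize_run <- function(out_dir) {
  out <- list()
  pj <- file.path(out_dir, "processes.json")
  if (file.exists(pj)) {
    p <- jsonlite::read_json(pj)
    rows <- lapply(names(p$per_group), function(g)
      data.frame(group = g, as.data.frame(p$per_group[[g]]$fractions),
                 stochastic = p$per_group[[g]]$stochastic))
    out$process_fractions <- do.call(rbind, rows)
    utils::write.table(out$process_fractions,
                       file.path(out_dir, "summary_process_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else message("processes.json missing; process block omitted")
  nj <- file.path(out_dir, "nst_groups.json")
  if (file.exists(nj)) {
    nstv <- unlist(jsonlite::read_json(nj))
    out$nst <- data.frame(group = names(nstv), nst_percent = nstv,
                          row.names = NULL)
    utils::write.table(out$nst, file.path(out_dir, "summary_nst.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else message("nst_groups.json missing; NST block omitted")
  tj <- file.path(out_dir, "network_topology.tsv")
  if (file.exists(tj)) {
    out$network <- utils::read.delim(tj, check.names = FALSE)
  } else message("network_topology.tsv missing; network block omitted")
  invisible(out)
}
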