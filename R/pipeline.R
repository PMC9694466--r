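#' Assemble a study configuration
#'
#' Every constant of the analysis protocol is surfaced as a named key with
#' its standard default: temperature 310 K, contact cutoff 4.5 A and
#' persistence 0.75 for networks, pocket zone 6 A and report threshold 30%
#' for fingerprints, RMSF gate 2 A, dominant-flux threshold 0.60, surface
#' tension 0.0072 kcal/(mol A^2) and probe 1.4 A for solvation.
#'
#' @param systems list of system descriptions; each a list with
#'   \code{name}, optional \code{ic50_nM}, and either \code{paths}
#'   (\code{dir}, \code{prefix}, for \code{\link{read_system}}) or
#'   \code{generate} (arguments for the toy generator: \code{n_frames},
#'   \code{noise_sd}, \code{hidden_T}, \code{open_shift}, \code{config}).
#' @param reference name of the reference system.
#' @param seed global integer seed.
#' @param temperature K.
#' @param rmsf_threshold flexible-residue gate (Angstrom).
#' @param k,lag,n_meta MSM parameters (microstate count, lag frames,
#'   metastate count).
#' @param pmf_bins PMF bins per axis.
#' @param pocket_cutoff,report_threshold fingerprint parameters.
#' @param dist_cutoff,persistence network parameters.
#' @param flux_threshold dominant-pathway cumulative flux fraction.
#' @param gamma,probe solvation parameters.
#' @param energy_frames number of evenly spaced frames scored by MM/GBSA
#'   (the snapshot-rescoring protocol, scaled to the trajectory length).
#' @param entropy_frames frames for normal-mode entropy (NULL skips it).
#' @param path_source,path_sink optional node labels for suboptimal-path
#'   analysis.
#' @param path_tolerance weight tolerance for suboptimal paths.
#' @return a \code{study_config} list.
#' @export
study_config <- function(systems, reference = systems[[1]]$name, seed = 1,
                         temperature = 310, rmsf_threshold = 2,
                         k = 20, lag = 1, n_meta = 2, pmf_bins = 40,
                         pocket_cutoff = 6, report_threshold = 30,
                         dist_cutoff = 4.5, persistence = 0.75,
                         flux_threshold = 0.60, gamma = 0.0072, probe = 1.4,
                         energy_frames = 50,
                         entropy_frames = NULL, path_source = NULL,
                         path_sink = NULL, path_tolerance = 1) {
  names(systems) <- vapply(systems, function(s) s$name, "")
  if (!(reference %in% names(systems)))
    .fail("reference system '%s' not in the system list", reference)
  structure(list(systems = systems, reference = reference, seed = seed,
                 temperature = temperature, rmsf_threshold = rmsf_threshold,
                 k = k, lag = lag, n_meta = n_meta, pmf_bins = pmf_bins,
                 pocket_cutoff = pocket_cutoff,
                 report_threshold = report_threshold,
                 dist_cutoff = dist_cutoff, persistence = persistence,
                 flux_threshold = flux_threshold, gamma = gamma,
                 probe = probe, energy_frames = energy_frames,
                 entropy_frames = entropy_frames,
                 path_source = path_source, path_sink = path_sink,
                 path_tolerance = path_tolerance),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the arguments of
#'   \code{\link{study_config}}; per-system \code{generate$hidden_T} is a
#'   nested list of rows.
#' @return a \code{study_config}.
#' @export
load_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (i in seq_along(y$systems)) {
    g <- y$systems[[i]]$generate
    if (!is.null(g$hidden_T))
      y$systems[[i]]$generate$hidden_T <-
        do.call(rbind, lapply(g$hidden_T, unlist))
  }
  do.call(study_config, y)
}

.load_system <- function(sys, cfg) {
  if (!is.null(sys$paths)) {
    got <- read_system(sys$paths$dir, sys$paths$prefix %||% "system")
    got$manifest <- NULL
    return(got)
  }
  g <- sys$generate %||% list()
  tc_args <- g$config %||% list()
  if (!is.null(g$open_shift)) tc_args$open_shift <- g$open_shift
  tc <- do.call(toy_config, tc_args)
  st <- generate_topology(tc)
  refs <- toy_state_refs(st, open_shift = tc$open_shift)
  hT <- g$hidden_T %||% matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  gen <- generate_trajectory(st, hT, refs[seq_len(nrow(hT))],
                             noise_sd = g$noise_sd %||% 0.5,
                             n_frames = g$n_frames %||% 500,
                             seed = split_seed(cfg$seed, sys$name))
  list(structure = st, trajectory = gen$trajectory,
       manifest = gen$manifest)
}

.analyze_system <- function(sys, cfg) {
  res <- list(name = sys$name, status = list())
  step <- function(nm, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(out, "error")
    res$status[[nm]] <<- list(
      ok = ok, seconds = round(proc.time()[["elapsed"]] - t0, 2),
      message = if (ok) "" else conditionMessage(out))
    if (ok) out else NULL
  }
  sysdata <- step("load", .load_system(sys, cfg))
  if (is.null(sysdata)) return(res)
  st <- sysdata$structure; tr <- sysdata$trajectory
  res$manifest <- sysdata$manifest

  res$geometry <- step("geometry", {
    prot <- select_atoms(st, role = "protein")
    ref <- .frame(tr, tr$ref_frame)
    rI <- rmsd_series(tr, ref, select_atoms(st, region = "LoopI"), prot)
    rII <- rmsd_series(tr, ref, select_atoms(st, region = "LoopII"), prot)
    rf <- residue_rmsf(tr, st)
    list(loopI_rmsd = rI, loopII_rmsd = rII, rmsf = rf,
         backbone_rmsd = rmsd_series(tr, ref, prot, prot))
  })

  res$msm <- step("msm", {
    flex <- select_flexible_residues(res$geometry$rmsf, cfg$rmsf_threshold)
    if (length(flex) == 0) {
      warning("no residues pass the RMSF gate; falling back to the loops",
              call. = FALSE)
      flex <- unlist(lapply(seq_len(nrow(st$regions)), function(i)
        seq(st$regions$start[i], st$regions$end[i])))
    }
    feats <- featurize(tr, st, flex)
    cl <- cluster_microstates(feats, min(cfg$k, nrow(unique(feats))),
                              seed = split_seed(cfg$seed,
                                                paste0("kmeans.", sys$name)))
    model <- estimate_msm(cl$dtraj, lag = cfg$lag)
    model <- coarse_grain_metastates(model,
                                     min(cfg$n_meta, nrow(model$T)))
    meta <- metastate_representatives(model, cl, feats, tr, st)
    src <- which(model$metastates$assignment ==
                 meta$metastate[meta$is_start])
    snk <- which(model$metastates$assignment == meta$metastate[meta$is_end])
    tpt <- if (length(intersect(src, snk)) == 0)
      tpt_flux_pathways(model, src, snk) else NULL
    dom <- if (!is.null(tpt))
      select_dominant_states(tpt, cfg$flux_threshold) else NULL
    list(flexible = flex, clustering = cl, model = model,
         metastates = meta, tpt = tpt, dominant = dom)
  })

  res$pmf <- step("pmf", {
    grid <- compute_pmf2d(res$geometry$loopI_rmsd, res$geometry$loopII_rmsd,
                          bins = cfg$pmf_bins, T = cfg$temperature)
    proj <- if (!is.null(res$msm))
      project_states_on_pmf(grid, res$msm$metastates) else NULL
    list(grid = grid, basins = locate_basins(grid), projection = proj)
  })

  lig <- select_atoms(st, role = "ligand")
  if (length(lig) > 0) {
    res$fingerprints <- step("fingerprints",
      interaction_frequencies(tr, st, lig,
                              report_threshold = cfg$report_threshold))
    res$energy <- step("energy", {
      rec <- setdiff(seq_len(nrow(st$atoms)), lig)
      fr <- unique(round(seq(1, n_frames(tr),
                             length.out = min(cfg$energy_frames %||% 50,
                                              n_frames(tr)))))
      mmgbsa_binding(tr, st, rec, lig, frames = fr, T = cfg$temperature,
                     entropy_frames = cfg$entropy_frames,
                     probe = cfg$probe, gamma = cfg$gamma)
    })
    res$decomposition <- step("decomposition",
      per_residue_decomposition(tr, st, lig,
                                frames = seq(1, n_frames(tr),
                                             length.out = min(25,
                                                              n_frames(tr))),
                                probe = cfg$probe, gamma = cfg$gamma))
  }

  res$network <- step("network", {
    net <- build_network(tr, st, cfg$dist_cutoff, cfg$persistence)
    comm <- detect_communities(net)
    pr <- if (!is.null(cfg$path_source) && !is.null(cfg$path_sink))
      suboptimal_paths(net, cfg$path_source, cfg$path_sink,
                       cfg$path_tolerance) else NULL
    list(net = net, communities = comm, paths = pr)
  })
  res
}

#' Run the full analysis pipeline over a study
#'
#' Executes every stage (geometry, MSM + TPT, PMF, fingerprints, MM/GBSA
#' energetics, dynamic network) per system, then the cross-system tables
#' (affinity ledger with ddG and r^2, fingerprint deltas and path-count
#' deltas against the reference system). Stage failures are recorded in
#' the per-system status and do not abort the rest of the bundle.
#'
#' @param config a \code{study_config}.
#' @return object of class \code{study_bundle}: \code{systems} (per-system
#'   results), \code{affinity}, \code{r_squared},
#'   \code{fingerprint_deltas}, \code{path_deltas}, \code{run_manifest}.
#' @export
run_pipeline <- function(config) {
  per <- lapply(config$systems, .analyze_system, cfg = config)
  names(per) <- names(config$systems)
  bundle <- list(systems = per)
  reports <- lapply(per, function(p) p$energy)
  have <- !vapply(reports, is.null, logical(1))
  if (any(have)) {
    ic <- vapply(config$systems, function(s)
      as.numeric(s$ic50_nM %||% NA), numeric(1))
    ref_ok <- config$reference %in% names(reports)[have]
    if (ref_ok) {
      bundle$affinity <- assemble_affinity_table(
        reports[have], ic[have], config$reference, T = config$temperature,
        allow_missing = TRUE)
      cc <- stats::complete.cases(bundle$affinity[, c("dG_exp", "dG_cal")])
      if (sum(cc) >= 3)
        bundle$r_squared <- r_squared(bundle$affinity$dG_cal[cc],
                                      bundle$affinity$dG_exp[cc])
    }
  }
  refp <- per[[config$reference]]
  if (!is.null(refp$fingerprints)) {
    bundle$fingerprint_deltas <- lapply(
      per[setdiff(names(per), config$reference)], function(p)
        if (!is.null(p$fingerprints))
          compare_fingerprints(refp$fingerprints, p$fingerprints))
  }
  refpaths <- refp$network$paths
  if (!is.null(refpaths)) {
    bundle$path_deltas <- lapply(
      per[setdiff(names(per), config$reference)], function(p)
        if (!is.null(p$network$paths))
          allosteric_path_delta(refpaths, p$network$paths))
  }
  cfg_txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  bundle$run_manifest <- list(
    seed = config$seed, config_hash = .text_hash(cfg_txt),
    temperature = config$temperature,
    systems = names(config$systems), reference = config$reference,
    status = lapply(per, function(p)
      vapply(p$status, function(s) s$ok, logical(1))))
  structure(bundle, class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("study_bundle:", length(x$systems), "systems\n")
  for (nm in names(x$systems)) {
    st <- x$systems[[nm]]$status
    ok <- vapply(st, function(s) s$ok, logical(1))
    cat(sprintf("  %-12s %s\n", nm,
                paste(ifelse(ok, names(ok), toupper(names(ok))),
                      collapse = " ")))
  }
  if (!is.null(x$r_squared))
    cat(sprintf("calculated-vs-experimental r^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Render report tables from a study bundle
#'
#' Produces the paper-style tables: the energy-ledger (components,
#' dE_bind, -TdS, dG_cal, ddG_cal, dG_exp, IC50 per system column), the
#' cross-system interaction-frequency table filtered at the report
#' threshold, and per-system path-count delta lists.
#'
#' @param bundle a \code{study_bundle}.
#' @param dir optional output directory; CSV files are written there.
#' @param threshold fingerprint report threshold (percent).
#' @return list with \code{energy}, \code{frequency}, \code{path_deltas}
#'   data.frames (where computable).
#' @export
render_tables <- function(bundle, dir = NULL, threshold = 30) {
  out <- list()
  reps <- lapply(bundle$systems, function(p) p$energy)
  have <- !vapply(reps, is.null, logical(1))
  if (any(have)) {
    rows <- c("dE_vdW", "dE_elec", "dE_covalent", "dG_solv", "dE_bind",
              "minus_TdS", "dG_cal")
    en <- data.frame(component = rows)
    for (nm in names(reps)[have])
      en[[nm]] <- vapply(rows, function(r) reps[[nm]][[r]], numeric(1))
    if (!is.null(bundle$affinity)) {
      extra <- data.frame(component = c("ddG_cal", "dG_exp", "ic50_nM"))
      for (nm in names(reps)[have]) {
        i <- match(nm, bundle$affinity$system)
        extra[[nm]] <- c(bundle$affinity$ddG_cal[i],
                         bundle$affinity$dG_exp[i],
                         bundle$affinity$ic50_nM[i])
      }
      en <- rbind(en, extra)
    }
    out$energy <- en
  }
  fps <- lapply(bundle$systems, function(p) p$fingerprints)
  fps <- fps[!vapply(fps, is.null, logical(1))]
  if (length(fps) > 0)
    out$frequency <- fingerprint_report(fps, threshold = threshold)
  if (!is.null(bundle$path_deltas))
    out$path_deltas <- bundle$path_deltas
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (!is.null(out$energy))
      write.csv(out$energy, file.path(dir, "energy_ledger.csv"),
                row.names = FALSE)
    if (!is.null(out$frequency))
      write.csv(out$frequency, file.path(dir, "interaction_frequencies.csv"),
                row.names = FALSE)
  }
  out
}
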