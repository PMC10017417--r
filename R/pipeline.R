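#' Default pipeline configuration
#'
#' A flat key-value list of every tunable parameter of the pipeline,
#' serializable as a `key = value` text file. Units are mm everywhere; the
#' gravity axis is +z.
#'
#' @return named list of class `podscan_config`.
#' @export
default_config <- function() {
  structure(list(
    # preprocessing
    outlier_k = 20, outlier_std_ratio = 2.0,
    pot_removal = TRUE, delta_d = 10, pot_grow_tol = 0.02, pot_margin = 2.0,
    # skeleton extraction
    r0 = NA, radius_growth = 0.5, r_final = 5, max_outer_iters = NA,
    inner_tol = 0.01,
    tau = 0.35, kernel_bandwidth_factor = 1.0, t_d = 1.5,
    ransac_iters = 20, ransac_inlier_tol = 1.0, sample_fraction = 0.07,
    max_points = 50000, constrain = TRUE,
    # connection
    eps = NA, min_pts = 3,
    # optimization
    merge_angle_max = 15, merge_dist_factor = 5, split_angle_min = 165,
    # traits
    branch_len_thresh = 200, floor_mm = 15, ci_z = 1.96,
    assign_radius = 3, extend_tips = TRUE, max_thickness = 2.2,
    chain_gap = 35, chain_angle = 20,
    # reproducibility
    seed = 1
  ), class = "podscan_config")
}

#' Read a configuration file
#'
#' Parses a flat `key = value` text file (comments start with `#`). Unknown
#' keys are rejected; keys not present keep their defaults.
#'
#' @param path file path.
#' @return a `podscan_config`.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line (expected 'key = value'): '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: '", key, "'")
    cfg[[key]] <- if (val %in% c("TRUE", "FALSE", "true", "false")) {
      as.logical(toupper(val))
    } else if (val == "NA") {
      NA
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop("config value for '", key, "' is not a number: '", val, "'")
      num
    }
  }
  cfg
}

#' Write a configuration file
#' @param config a `podscan_config`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v)
    if (is.logical(v)) as.character(v) else format(v, digits = 15), "")
  writeLines(paste(names(config), "=", vals), path)
  invisible(path)
}

.cfg_na_null <- function(x) if (is.na(x)) NULL else x

#' Run the full silique phenotyping pipeline
#'
#' preprocess (statistical outlier filter, pot detection and removal) ->
#' skeletonize (L1-median contraction under the RANSAC plane constraint) ->
#' connect (DBSCAN + ordered polyline growth) -> optimize (merge/split
#' repair) -> traits (branch classification, effective-silique filter, point
#' assignment, volumes). When `output_dir` is given, writes the skeleton
#' CSV, sub-skeleton edge list, labeled cloud (PLY), per-silique CSV, a
#' summary JSON embedding the fully resolved configuration, and a log with
#' per-stage timings and counts.
#'
#' @param input a [point_cloud()] or a file path readable by [read_cloud()].
#' @param config a `podscan_config` (or path to one).
#' @param output_dir optional output directory.
#' @param name file stem for artifacts (default "plant").
#' @return a [plant_traits()] object, with the intermediate stages attached
#'   as attribute `"stages"`.
#' @export
run_pipeline <- function(input, config = default_config(), output_dir = NULL,
                         name = "plant") {
  if (is.character(config)) config <- read_config(config)
  cloud <- if (inherits(input, "point_cloud")) input else read_cloud(input)
  if (n_points(cloud) == 0) stop("stage preprocess failed: empty input cloud")
  log <- character(0)
  stamp <- function(stage, t0, msg) {
    log <<- c(log, sprintf("%-12s %6.2f s  %s", stage,
                           as.numeric(Sys.time()) - t0, msg))
  }

  t0 <- as.numeric(Sys.time())
  work <- tryCatch({
    w <- remove_outliers(cloud, k = config$outlier_k,
                         std_ratio = config$outlier_std_ratio)
    if (isTRUE(config$pot_removal)) {
      pot <- detect_pot(w, delta_d = config$delta_d,
                        grow_tol = config$pot_grow_tol)
      w <- remove_pot(w, pot, margin = config$pot_margin)
    }
    w
  }, error = function(e) stop("stage preprocess failed: ",
                              conditionMessage(e)))
  stamp("preprocess", t0, sprintf("%d -> %d points", n_points(cloud),
                                  n_points(work)))

  t0 <- as.numeric(Sys.time())
  skel <- tryCatch({
    sp <- skeleton_params(
      r0 = .cfg_na_null(config$r0), radius_growth = config$radius_growth,
      r_final = config$r_final,
      max_outer_iters = .cfg_na_null(config$max_outer_iters),
      inner_tol = config$inner_tol,
      tau = config$tau,
      kernel_bandwidth_factor = config$kernel_bandwidth_factor,
      T_d = config$t_d, ransac_iters = config$ransac_iters,
      ransac_inlier_tol = config$ransac_inlier_tol,
      sample_fraction = config$sample_fraction,
      max_points = config$max_points,
      constrain = isTRUE(config$constrain), seed = config$seed)
    extract_skeleton(work, sp)
  }, error = function(e) stop("stage skeletonize failed: ",
                              conditionMessage(e)))
  stamp("skeletonize", t0, sprintf("%d skeleton points, %d iterations",
                                   nrow(skel$positions),
                                   length(skel$movement_trace)))

  t0 <- as.numeric(Sys.time())
  subs <- tryCatch(
    connect_skeleton(skel, eps = .cfg_na_null(config$eps),
                     min_pts = config$min_pts),
    error = function(e) stop("stage connect failed: ", conditionMessage(e)))
  stamp("connect", t0, sprintf("%d sub-skeletons", length(subs)))

  t0 <- as.numeric(Sys.time())
  opt <- tryCatch(
    optimize_subskeletons(subs, optimize_params(
      merge_angle_max = config$merge_angle_max,
      merge_dist_factor = config$merge_dist_factor,
      split_angle_min = config$split_angle_min)),
    error = function(e) stop("stage optimize failed: ", conditionMessage(e)))
  stamp("optimize", t0, sprintf("%d sub-skeletons", length(opt)))

  t0 <- as.numeric(Sys.time())
  traits <- tryCatch(
    plant_traits(opt, work, trait_params(
      branch_len_thresh = config$branch_len_thresh,
      floor_mm = config$floor_mm, z = config$ci_z, T_d = config$t_d,
      assign_radius = config$assign_radius,
      extend_tips = isTRUE(config$extend_tips),
      max_thickness = config$max_thickness,
      chain_gap = config$chain_gap, chain_angle = config$chain_angle,
      seed = config$seed)),
    error = function(e) stop("stage traits failed: ", conditionMessage(e)))
  stamp("traits", t0, sprintf("SN = %d, total SL = %.1f mm, total SV = %.1f mm^3",
                              traits$sn_e, traits$total_sl, traits$total_sv))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_skeleton_csv(skel, file.path(output_dir, paste0(name, "_skeleton.csv")))
    write_subskeletons_csv(opt, file.path(output_dir, paste0(name, "_subskeletons.csv")))
    write_cloud(label_cloud(traits, work),
                file.path(output_dir, paste0(name, "_labeled.ply")))
    write.csv(traits$siliques,
              file.path(output_dir, paste0(name, "_siliques.csv")),
              row.names = FALSE)
    summary <- list(sn_e = traits$sn_e, total_sl = traits$total_sl,
                    total_sv = traits$total_sv,
                    n_branches = traits$n_branches,
                    n_candidates = nrow(traits$siliques),
                    config = unclass(config))
    jsonlite::write_json(summary,
                         file.path(output_dir, paste0(name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log, file.path(output_dir, paste0(name, "_log.txt")))
  }
  attr(traits, "stages") <- list(preprocessed = work, skeleton = skel,
                                 subskeletons = opt, log = log)
  traits
}

#' Evaluate the pipeline on synthetic plants
#'
#' Runs [run_pipeline()] on each generated plant and scores it against the
#' generator's ground truth: per-plant recalls (the true silique count
#' serves as both the cloud count SN_L and the manual count SN_M) and, with
#' two or more plants, agreement statistics (R^2, RMSE, Pearson R) across
#' plants for SN, total SL and total SV.
#'
#' @param plants list of lists with elements `cloud` and `truth` (as
#'   produced by [generate_plant()]).
#' @param config a `podscan_config`.
#' @return list of class `podscan_eval`: per-plant table and, when
#'   available, the agreement statistics.
#' @export
run_eval <- function(plants, config = default_config()) {
  stopifnot(length(plants) >= 1)
  rows <- lapply(seq_along(plants), function(i) {
    pl <- plants[[i]]
    tr <- run_pipeline(pl$cloud, config = config)
    rec <- recalls(tr$sn_e, pl$truth$sn, pl$truth$sn)
    data.frame(plant = i, sn_true = pl$truth$sn, sn_e = tr$sn_e,
               re_el = rec$re_el, re_em = rec$re_em,
               total_sl = tr$total_sl, total_sl_true = pl$truth$total_sl,
               total_sv = tr$total_sv, total_sv_true = pl$truth$total_sv)
  })
  tab <- do.call(rbind, rows)
  agr <- NULL
  if (nrow(tab) >= 2 && sd(tab$sn_true) > 0) {
    agr <- list(sn = agreement(tab$sn_e, tab$sn_true),
                total_sl = agreement(tab$total_sl, tab$total_sl_true),
                total_sv = agreement(tab$total_sv, tab$total_sv_true))
  } else {
    message("single plant (or constant truth): agreement statistics skipped")
  }
  structure(list(per_plant = tab, agreement = agr,
                 mean_re_el = mean(tab$re_el),
                 mean_sl_rel_err = mean(abs(tab$total_sl - tab$total_sl_true) /
                                          tab$total_sl_true),
                 mean_sv_rel_err = mean(abs(tab$total_sv - tab$total_sv_true) /
                                          tab$total_sv_true)),
            class = "podscan_eval")
}

#' @export
print.podscan_eval <- function(x, ...) {
  cat(sprintf("podscan_eval: %d plant(s)\n", nrow(x$per_plant)))
  cat(sprintf("  mean Re_EL = %.1f%%, mean |dSL|/SL = %.1f%%, mean |dSV|/SV = %.1f%%\n",
              x$mean_re_el, 100 * x$mean_sl_rel_err, 100 * x$mean_sv_rel_err))
  if (!is.null(x$agreement))
    cat(sprintf("  R2: SN %.3f, total SL %.3f, total SV %.3f\n",
                x$agreement$sn$r2, x$agreement$total_sl$r2,
                x$agreement$total_sv$r2))
  invisible(x)
}
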