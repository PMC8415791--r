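#' Configuration of a single-case LSA quantification run
#'
#' Collects all inputs and parameters of the end-to-end pipeline
#' (bias-correct, enhance, restrict to ROI, threshold, extract, quantify,
#' morphometry). Inputs may be in-memory objects or file paths; paths are
#' resolved at run time.
#'
#' @param volume a [scalar_volume()] or NIfTI path.
#' @param regions a [region_mask()] or NIfTI path (with `legend`).
#' @param legend legend sidecar path (YAML/JSON), required when `regions`
#'   is a path.
#' @param transform optional 4x4 world-to-world affine (matrix or text
#'   path) used to resample the region mask onto the volume grid.
#' @param quant_regions region names over which vascular volume is
#'   quantified (default: every legend entry except the parent artery).
#' @param parent_region legend name of the parent-artery rooting region,
#'   or NULL to skip morphometry (unless `seed_voxel` is given).
#' @param vessel_params a [vesselness_params()].
#' @param bias_fwhm bias-field smoothing FWHM in mm; NULL disables the
#'   bias-correction stage.
#' @param step_percent,delta_star threshold-selection controls, see
#'   [select_threshold()].
#' @param seed_voxel optional 1-based voxel triple for seeded component
#'   retention and rooting.
#' @param out_dir output directory for the report bundle; NULL keeps
#'   results in memory only.
#' @param id case identifier used in reports.
#' @return object of class `case_config`.
#' @export
case_config <- function(volume, regions, legend = NULL, transform = NULL,
                        quant_regions = NULL, parent_region = "parent_artery",
                        vessel_params = vesselness_params(),
                        bias_fwhm = 40, step_percent = 0.5, delta_star = 0.2,
                        seed_voxel = NULL, out_dir = NULL, id = "case") {
  stopifnot(delta_star > 0)
  structure(list(volume = volume, regions = regions, legend = legend,
                 transform = transform, quant_regions = quant_regions,
                 parent_region = parent_region,
                 vessel_params = vessel_params, bias_fwhm = bias_fwhm,
                 step_percent = step_percent, delta_star = delta_star,
                 seed_voxel = seed_voxel, out_dir = out_dir, id = id),
            class = "case_config")
}

#' Build a case configuration from a YAML file
#'
#' Mirrors [case_config()]; path fields are resolved relative to the YAML
#' file's directory. Recognised keys: `volume`, `regions`, `legend`,
#' `transform`, `quant_regions`, `parent_region`, `bias_fwhm`,
#' `step_percent`, `delta_star`, `seed_voxel`, `out_dir`, `id`, and a
#' `vesselness` block with `d_min`, `d_max`, `n_scales`, `alpha`, `beta`,
#' `contrast`.
#'
#' @param path YAML file.
#' @return a [case_config()].
#' @export
case_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    if (file.exists(p)) p else file.path(base, p)
  vp <- do.call(vesselness_params, if (is.null(y$vesselness)) list()
                else y$vesselness)
  case_config(volume = rel(y$volume), regions = rel(y$regions),
              legend = rel(y$legend), transform = rel(y$transform),
              quant_regions = y$quant_regions,
              parent_region = if (is.null(y$parent_region)) "parent_artery"
                              else y$parent_region,
              vessel_params = vp,
              bias_fwhm = if (is.null(y$bias_fwhm)) 40 else y$bias_fwhm,
              step_percent = if (is.null(y$step_percent)) 0.5
                             else y$step_percent,
              delta_star = if (is.null(y$delta_star)) 0.2 else y$delta_star,
              seed_voxel = y$seed_voxel,
              out_dir = if (is.null(y$out_dir)) NULL else rel(y$out_dir),
              id = if (is.null(y$id)) "case" else y$id)
}

#' Case configuration for a synthetic phantom
#'
#' @param phantom an [lsa_phantom()].
#' @param ... overrides passed to [case_config()].
#' @return a [case_config()].
#' @export
phantom_case_config <- function(phantom, ...) {
  stopifnot(inherits(phantom, "lsa_phantom"))
  args <- list(volume = phantom$volume, regions = phantom$regions,
               quant_regions = phantom$subcortical_regions,
               id = paste0("phantom-", phantom$seed))
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(case_config, args)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Run the end-to-end case pipeline
#'
#' Executes, in order: bias correction, multiscale vesselness, restriction
#' to the subcortical ROI, volume-ratio threshold selection, vessel
#' extraction, per-region volumetry, large-vessel QC, and skeleton
#' morphometry. The run is deterministic given the configuration. When
#' `out_dir` is set, a report bundle is written: `enhanced.nii.gz`,
#' `vessel_mask.nii.gz`, `volumes.json`, `morpho.json`, `qc.json`,
#' `provenance.json`; any stage error aborts with the stage name, with the
#' outputs of completed stages preserved.
#'
#' @param config a [case_config()] (or an [lsa_phantom()], which is wrapped
#'   via [phantom_case_config()]).
#' @return object of class `lsa_case_report`: inputs echoed plus
#'   `enhanced`, `selection`, `vessel_mask`, `volumes`, `qc`, `graph`,
#'   `morphometry`, `excluded`.
#' @export
run_case <- function(config) {
  if (inherits(config, "lsa_phantom")) config <- phantom_case_config(config)
  stopifnot(inherits(config, "case_config"))
  res <- list(id = config$id)
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  current_stage <- "setup"
  stage <- function(name, expr) {
    current_stage <<- name
    expr
  }
  tryCatch({
    vol <- stage("load_volume",
                 if (is.character(config$volume)) read_volume(config$volume)
                 else config$volume)
    roi <- stage("load_regions", {
      r <- if (is.character(config$regions))
        read_region_mask(config$regions, config$legend)
      else config$regions
      tr <- config$transform
      if (is.character(tr)) tr <- read_affine(tr)
      if (!is.null(tr) || !all(dim(r$labels) == dim(vol$data)))
        r <- resample_mask_to_grid(r, if (is.null(tr)) diag(4) else tr, vol)
      r
    })
    quant_regions <- config$quant_regions
    if (is.null(quant_regions))
      quant_regions <- setdiff(names(roi$legend), config$parent_region)

    corrected <- stage("bias_correction",
                       if (is.null(config$bias_fwhm)) list(volume = vol)
                       else correct_bias(vol, config$bias_fwhm))
    enhanced <- stage("vesselness",
                      vesselness(corrected$volume, config$vessel_params))
    restricted <- stage("restrict_to_roi",
                        restrict_to_regions(enhanced, roi, quant_regions))
    selection <- stage("select_threshold",
                       select_threshold(restricted, roi, quant_regions,
                                        step_percent = config$step_percent,
                                        delta_star = config$delta_star))
    vessel_mask <- stage("extract_vessels",
                         extract_vessels(restricted, selection, roi,
                                         quant_regions,
                                         seed_voxel = config$seed_voxel))
    volumes <- stage("quantify_volumes",
                     quantify_region_volumes(vessel_mask, roi, quant_regions))
    qc <- stage("qc_large_vessels",
                flag_large_vessels(vessel_mask, vol$spacing,
                                   d_max = config$vessel_params$d_max))
    res$enhanced <- enhanced
    res$selection <- selection
    res$vessel_mask <- vessel_mask
    res$volumes <- volumes
    res$qc <- qc
    morpho <- stage("morphometry", {
      parent <- NULL
      if (!is.null(config$parent_region) &&
          config$parent_region %in% names(roi$legend))
        parent <- roi$labels == roi$legend[[config$parent_region]]
      if ((is.null(parent) || !any(parent)) && is.null(config$seed_voxel)) {
        NULL
      } else if (!any(vessel_mask)) {
        NULL
      } else {
        # stems attach to the parent artery outside the subcortical ROI, so
        # the skeleton is traced on the whole-grid suprathreshold mask,
        # keeping only components connected to the parent region (or seed)
        thr_mask <- enhanced$data >= selection$selected_threshold
        if (!is.null(parent) && any(parent)) {
          d <- dim(thr_mask)
          lab <- array(.cpp_label_components(thr_mask, d, 26L), dim = d)
          ids <- unique(lab[dilate26(parent) & lab > 0])
          morpho_mask <- array(lab %in% ids, dim = d)
        } else {
          morpho_mask <- extract_vessels(enhanced, selection,
                                         seed_voxel = config$seed_voxel)
        }
        g <- skeletonize_to_graph(morpho_mask, vol$spacing,
                                  parent_mask = parent,
                                  seed_voxel = config$seed_voxel)
        counts <- count_stems_branches(g)
        list(graph = g,
             n_stems = unname(counts["n_stems"]),
             n_branches = unname(counts["n_branches"]),
             longest_length_cm = longest_vessel_length(g))
      }
    })

    res$graph <- morpho$graph
    res$morphometry <- if (is.null(morpho)) NULL else
      morpho[c("n_stems", "n_branches", "longest_length_cm")]
    res$excluded <- !qc$pass
    res$config <- config
  }, error = function(e) {
    if (!is.null(out)) try(flush_case_outputs(res, out, config), silent = TRUE)
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })

  if (!is.null(out)) flush_case_outputs(res, out, config)
  structure(res, class = "lsa_case_report")
}

# write whichever artifacts of a (possibly partial) case result exist
flush_case_outputs <- function(res, out, config) {
  if (!is.null(res$enhanced)) {
    write_volume(res$enhanced, file.path(out, "enhanced.nii.gz"))
    if (!is.null(res$vessel_mask))
      write_volume(scalar_volume(array(as.numeric(res$vessel_mask),
                                       dim = dim(res$vessel_mask)),
                                 spacing = res$enhanced$spacing,
                                 affine = res$enhanced$affine),
                   file.path(out, "vessel_mask.nii.gz"))
  }
  if (!is.null(res$volumes)) {
    pr <- res$volumes$per_region
    write_json_report(list(
      selected_threshold = res$selection$selected_threshold,
      curves = list(candidates = res$selection$candidates,
                    volume_curve = res$selection$volume_curve,
                    ratio_change_curve = res$selection$ratio_change_curve),
      per_region = stats::setNames(lapply(seq_len(nrow(pr)), function(i)
        list(voxels = pr$voxels[i], volume_mm3 = pr$volume_mm3[i],
             fraction = pr$fraction[i])), pr$region),
      total = list(voxels = res$volumes$total_voxel_count,
                   volume_mm3 = res$volumes$total_volume_mm3,
                   voxel_volume_mm3 = res$volumes$voxel_volume_mm3)),
      file.path(out, "volumes.json"))
  }
  write_json_report(if (is.null(res$morphometry))
    list(available = FALSE) else c(list(available = TRUE),
                                   res$morphometry),
    file.path(out, "morpho.json"))
  if (!is.null(res$qc))
    write_json_report(list(pass = res$qc$pass,
                           excluded = isTRUE(res$excluded),
                           radius_limit_mm = res$qc$radius_limit_mm,
                           components = res$qc$components),
                      file.path(out, "qc.json"))
  write_json_report(list(
    id = config$id,
    package_version = as.character(utils::packageVersion("lsavol")),
    vesselness = unclass(config$vessel_params),
    bias_fwhm = config$bias_fwhm,
    step_percent = config$step_percent,
    delta_star = config$delta_star,
    quant_regions = config$quant_regions,
    parent_region = config$parent_region,
    seed_voxel = config$seed_voxel,
    grid = if (!is.null(res$enhanced)) dim(res$enhanced$data),
    spacing = if (!is.null(res$enhanced)) res$enhanced$spacing),
    file.path(out, "provenance.json"))
  invisible(out)
}

#' @export
print.lsa_case_report <- function(x, ...) {
  cat(sprintf("<lsa_case_report> %s: %d vessel voxels, %.4g mm^3%s\n",
              x$id, x$volumes$total_voxel_count, x$volumes$total_volume_mm3,
              if (x$excluded) " [EXCLUDED by QC]" else ""))
  if (!is.null(x$morphometry))
    cat(sprintf("  stems %d, branches %d, longest %.3g cm\n",
                x$morphometry$n_stems, x$morphometry$n_branches,
                x$morphometry$longest_length_cm))
  invisible(x)
}

#' Run a cohort of cases and aggregate statistics
#'
#' Aggregates per-case vascular volumes and morphometry into one table,
#' summarises each measure as mean +/- SD, and correlates vascular volume
#' with the number of branches, the number of stems and the maximal length.
#' QC-excluded cases are listed and excluded from the statistics, never
#' silently dropped.
#'
#' @param cases list of [case_config()]s, [lsa_phantom()]s or
#'   [run_case()] results (>= 2 valid cases required).
#' @return object of class `lsa_cohort_report`: `table` (one row per
#'   case), `summaries`, `correlations`, `excluded` (case ids).
#' @export
run_cohort <- function(cases) {
  if (length(cases) < 2) stop("cohort error: need at least 2 cases")
  reports <- lapply(cases, function(cs)
    if (inherits(cs, "lsa_case_report")) cs else run_case(cs))
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(id = r$id,
               volume_mm3 = r$volumes$total_volume_mm3,
               n_stems = if (is.null(r$morphometry)) NA_integer_
                         else r$morphometry$n_stems,
               n_branches = if (is.null(r$morphometry)) NA_integer_
                            else r$morphometry$n_branches,
               longest_cm = if (is.null(r$morphometry)) NA_real_
                            else r$morphometry$longest_length_cm,
               excluded = r$excluded)))
  keep <- !tab$excluded
  if (sum(keep) < 2)
    stop("cohort error: fewer than 2 cases passed QC")
  inc <- tab[keep, ]
  summaries <- lapply(inc[c("volume_mm3", "n_stems", "n_branches",
                            "longest_cm")],
                      function(v) if (all(is.na(v))) c(mean = NA, sd = NA)
                      else summarize_mean_sd(v[!is.na(v)]))
  corr_with <- function(v) {
    ok <- !is.na(v) & !is.na(inc$volume_mm3)
    if (sum(ok) < 3 || var(v[ok]) == 0) return(list(r = NA, p = NA, n = sum(ok)))
    pearson_correlation(inc$volume_mm3[ok], v[ok])
  }
  correlations <- list(volume_vs_branches = corr_with(inc$n_branches),
                       volume_vs_stems = corr_with(inc$n_stems),
                       volume_vs_length = corr_with(inc$longest_cm))
  structure(list(table = tab, summaries = summaries,
                 correlations = correlations,
                 excluded = tab$id[tab$excluded]),
            class = "lsa_cohort_report")
}

#' @export
print.lsa_cohort_report <- function(x, ...) {
  cat(sprintf("<lsa_cohort_report> %d case(s), %d excluded by QC\n",
              nrow(x$table), length(x$excluded)))
  s <- x$summaries
  cat(sprintf("  volume %.4g +/- %.3g mm^3; stems %.3g +/- %.2g; branches %.3g +/- %.2g; longest %.3g +/- %.2g cm\n",
              s$volume_mm3["mean"], s$volume_mm3["sd"],
              s$n_stems["mean"], s$n_stems["sd"],
              s$n_branches["mean"], s$n_branches["sd"],
              s$longest_cm["mean"], s$longest_cm["sd"]))
  for (nm in names(x$correlations)) {
    cc <- x$correlations[[nm]]
    cat(sprintf("  %s: r = %.3f, p = %.4g (n = %d)\n", nm,
                cc$r, cc$p, cc$n))
  }
  invisible(x)
}
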