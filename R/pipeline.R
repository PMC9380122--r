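#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end workflow. Exactly one of
#' \code{phantom} (a \code{phantom_spec}: the case is generated
#' synthetically) or \code{paths} (named list of NIfTI paths for a real
#' case) must be given. For file input the required names are
#' \code{pre_volume}, \code{pre_liver}, \code{pre_gtv}, \code{post_volume},
#' \code{post_liver}, \code{post_ablation}; the recurrence stage
#' additionally needs \code{recur_volume}, \code{recur_liver},
#' \code{recur_ablation}, \code{recur_recurrence}.
#'
#' @param phantom optional \code{phantom_spec}.
#' @param paths optional named list of file paths.
#' @param meshing \code{meshing_params}.
#' @param elastic \code{elastic_params}.
#' @param margin \code{margin_params}.
#' @param vesselness \code{vesselness_params}.
#' @param focused \code{focused_reg_params}.
#' @param cone_bin_deg,cone_dilation_deg cone-tracing angular resolution and
#'   dilation (degrees).
#' @param manual_post_to_recur optional externally supplied
#'   \code{rigid_transform} used when the focused vessel registration
#'   signals insufficient vasculature.
#' @param out_dir optional output directory for artifacts and reports.
#' @param seed integer seed (echoed to the log; used by phantom generation).
#' @param verbose log stage progress and timings to stderr.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(phantom = NULL, paths = NULL,
                            meshing = meshing_params(),
                            elastic = elastic_params(),
                            margin = margin_params(),
                            vesselness = vesselness_params(),
                            focused = focused_reg_params(),
                            cone_bin_deg = 2, cone_dilation_deg = 0,
                            manual_post_to_recur = NULL,
                            out_dir = NULL, seed = 1L, verbose = TRUE) {
  if (is.null(phantom) == is.null(paths))
    stop("exactly one of phantom spec or input paths must be given")
  structure(list(phantom = phantom, paths = paths, meshing = meshing,
                 elastic = elastic, margin = margin,
                 vesselness = vesselness, focused = focused,
                 cone_bin_deg = cone_bin_deg,
                 cone_dilation_deg = cone_dilation_deg,
                 manual_post_to_recur = manual_post_to_recur,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

read_pipeline_inputs <- function(paths) {
  vol <- function(nm, mask = FALSE) {
    if (is.null(paths[[nm]])) return(NULL)
    read_volume(paths[[nm]], mask = if (mask) TRUE else NULL)
  }
  inp <- list(
    pre = list(volume = vol("pre_volume"),
               masks = list(liver = vol("pre_liver", TRUE),
                            gtv = vol("pre_gtv", TRUE))),
    post = list(volume = vol("post_volume"),
                masks = list(liver = vol("post_liver", TRUE),
                             ablation = vol("post_ablation", TRUE))))
  if (!is.null(paths$recur_volume))
    inp$recur <- list(volume = vol("recur_volume"),
                      masks = list(liver = vol("recur_liver", TRUE),
                                   ablation_shrunk = vol("recur_ablation", TRUE),
                                   recurrence = vol("recur_recurrence", TRUE)))
  for (tp in names(inp)) {
    for (nm in names(inp[[tp]]$masks))
      if (!is.null(inp[[tp]]$masks[[nm]]))
        stop_if_geometry_mismatch(inp[[tp]]$volume, inp[[tp]]$masks[[nm]])
  }
  inp
}

#' Run the end-to-end ablation-assessment pipeline
#'
#' Chains rigid plus biomechanical registration of the pre-treatment scan
#' onto the post-ablation scan, propagation of the tumor contour, 3D
#' minimum-margin computation (under both rigid-only and deformable
#' mapping), and — when a recurrence time point is available — vesselness
#' segmentation, sphere-of-interest focused rigid registration and the
#' cone-tracing colocation test. Insufficient vasculature does not abort
#' the run: it is flagged in the report and the externally supplied manual
#' transform (if any) is used instead.
#'
#' @param config a \code{pipeline_config}.
#' @return report list with elements \code{margin_deformed},
#'   \code{margin_rigid}, \code{cone} (or NULL), \code{flags},
#'   \code{timings_s}, \code{registration}, and phantom ground-truth
#'   diagnostics when applicable.
#' @export
run_pipeline <- function(config) {
  log <- function(...) if (config$verbose)
    message(sprintf("[ablmargin] %s", sprintf(...)))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stagetime <- function(nm, t0) {
    timings[[nm]] <<- round(tic() - t0, 2)
    log("%-28s %.1f s", nm, timings[[nm]])
  }
  log("seed = %d", config$seed)

  t0 <- tic()
  if (!is.null(config$phantom)) {
    case <- generate_phantom(config$phantom)
  } else {
    case <- read_pipeline_inputs(config$paths)
  }
  stagetime("inputs", t0)

  t0 <- tic()
  reg <- biomech_register(case$pre$volume, case$pre$masks$liver,
                          case$post$volume, case$post$masks$liver,
                          meshing = config$meshing,
                          elastic = config$elastic,
                          focus = case$pre$masks$gtv)
  stagetime("biomech_register", t0)

  t0 <- tic()
  post_grid <- case$post$masks$liver
  gtv_def <- propagate_contour(case$pre$masks$gtv, reg$dvf, "forward",
                               post_grid)
  gtv_rig <- propagate_contour(case$pre$masks$gtv, reg$rigid, "forward",
                               post_grid)
  m_def <- min_margin(gtv_def, case$post$masks$ablation,
                      case$post$masks$liver, config$margin)
  m_rig <- min_margin(gtv_rig, case$post$masks$ablation,
                      case$post$masks$liver, config$margin)
  stagetime("margin", t0)

  flags <- character(0)
  cone <- NULL
  focused_tf <- NULL
  if (!is.null(case$recur)) {
    t0 <- tic()
    post_vessels <- segment_vessels(case$post$volume, case$post$masks$liver,
                                    config$vesselness)
    recur_vessels <- segment_vessels(case$recur$volume,
                                     case$recur$masks$liver,
                                     config$vesselness)
    stagetime("segment_vessels", t0)

    t0 <- tic()
    focused_tf <- tryCatch(
      focused_vessel_registration(post_vessels, recur_vessels,
                                  case$post$masks$ablation,
                                  case$recur$masks$ablation_shrunk,
                                  config$focused),
      insufficient_vasculature = function(e) {
        flags <<- c(flags, "insufficient_vasculature")
        log("focused registration: %s", conditionMessage(e))
        config$manual_post_to_recur
      })
    stagetime("focused_registration", t0)

    if (!is.null(focused_tf)) {
      t0 <- tic()
      rec_centroid <- mask_centroid(case$recur$masks$ablation_shrunk)
      dirset <- build_direction_set(rec_centroid,
                                    case$recur$masks$recurrence,
                                    bin_deg = config$cone_bin_deg,
                                    dilation_deg = config$cone_dilation_deg)
      post_centroid <- mask_centroid(case$post$masks$ablation)
      cone <- cone_overlap(dirset, post_centroid, m_def$uncovered_region,
                           focused_tf)
      stagetime("cone_tracing", t0)
    } else {
      flags <- c(flags, "cone_tracing_skipped_no_transform")
    }
  }

  report <- list(margin_deformed = m_def, margin_rigid = m_rig,
                 cone = cone, flags = flags,
                 registration = list(rigid = reg$rigid,
                                     focused = focused_tf),
                 timings_s = unlist(timings), seed = config$seed)
  if (!is.null(config$phantom)) {
    # ground-truth diagnostics available for synthetic cases
    tn <- reg$mesh$surface_vertex_ids
    pts <- reg$mesh$nodes[tn, , drop = FALSE]
    tru <- sample_dvf(case$truth$dvf, pts)
    tre <- sqrt(rowSums((reg$node_displacements[tn, ] - tru)^2))
    report$truth <- list(
      mean_surface_tre_mm = mean(tre),
      gtv_dice_deformed = dice_coef(gtv_def, case$truth$gtv_post),
      gtv_dice_rigid = dice_coef(gtv_rig, case$truth$gtv_post))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    t0 <- tic()
    write_pipeline_outputs(config, case, reg, gtv_def, report)
    stagetime("write_outputs", t0)
  }
  report
}

write_pipeline_outputs <- function(config, case, reg, gtv_def, report) {
  od <- config$out_dir
  if (!is.null(config$phantom)) write_phantom(case, file.path(od, "phantom"))
  write_dvf(reg$dvf, file.path(od, "dvf_pre_to_post"))
  write_rigid(reg$rigid, file.path(od, "rigid_pre_to_post.txt"))
  write_mesh_ply(reg$surface_mesh_pre, file.path(od, "liver_pre.ply"))
  write_mesh_ply(reg$surface_mesh_post, file.path(od, "liver_post.ply"))
  write_volume(gtv_def, file.path(od, "gtv_mapped_deformed"))
  write_volume(report$margin_deformed$uncovered_region,
               file.path(od, "uncovered_margin_region"))
  if (!is.null(report$cone))
    write_volume(report$cone$overlap_mask, file.path(od, "cone_overlap"))
  summary <- data.frame(
    quantity = c("min_margin_deformed_mm", "min_margin_rigid_mm",
                 "pct_gtv_outside_deformed", "pct_gtv_outside_rigid",
                 "cc_gtv_outside_deformed", "cc_gtv_outside_rigid",
                 "cone_overlap", "cone_overlap_cc"),
    value = c(report$margin_deformed$min_margin,
              report$margin_rigid$min_margin,
              report$margin_deformed$pct_gtv_outside,
              report$margin_rigid$pct_gtv_outside,
              report$margin_deformed$cc_gtv_outside,
              report$margin_rigid$cc_gtv_outside,
              if (is.null(report$cone)) NA else as.numeric(report$cone$overlap),
              if (is.null(report$cone)) NA else report$cone$overlap_volume_cc))
  write.csv(summary, file.path(od, "report.csv"), row.names = FALSE)
  json <- list(
    seed = config$seed,
    flags = as.list(report$flags),
    min_margin_deformed_mm = report$margin_deformed$min_margin,
    min_margin_rigid_mm = report$margin_rigid$min_margin,
    pct_gtv_outside_deformed = report$margin_deformed$pct_gtv_outside,
    pct_gtv_outside_rigid = report$margin_rigid$pct_gtv_outside,
    cone_overlap = if (is.null(report$cone)) NULL else report$cone$overlap,
    cone_overlap_cc = if (is.null(report$cone)) NULL
                      else report$cone$overlap_volume_cc,
    timings_s = as.list(report$timings_s),
    truth = report$truth,
    config = list(
      meshing = unclass(config$meshing), elastic = unclass(config$elastic),
      margin = unclass(config$margin),
      vesselness = unclass(config$vesselness),
      focused = unclass(config$focused),
      cone_bin_deg = config$cone_bin_deg,
      cone_dilation_deg = config$cone_dilation_deg))
  jsonlite::write_json(json, file.path(od, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(od)
}
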