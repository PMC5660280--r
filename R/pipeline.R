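# Small FNV-1a hash over the serialized config text, used to tag run logs so
# reruns of an identical config are recognisable.
.fnv1a <- function(text) {
  bytes <- utf8ToInt(text)
  h <- 216613626
  for (b in bytes) {
    # polynomial rolling hash kept inside exact double-precision integers
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Read and validate an analysis configuration
#'
#' The configuration is a YAML file with (all optional unless a stage needs
#' them): `trajectory` / `empty_trajectory` (PDB paths), `seed`, `output_dir`,
#' `ion` (center selection), `rdf` (`partners`, `bin_width`, `r_max`,
#' `cutoff`), `denticity` (`oxygen_pair`, `cutoff`), `hbonds` (list of
#' contacts with `label`, `donor`, `hydrogen`, `acceptor` selections),
#' `hbond_criteria` (`max_ha_distance`, `max_deviation_angle`,
#' `angle_vertex`), `distances` (list of `label`/`group_a`/`group_b`),
#' `stacking` (list of `label`/`ring_a`/`ring_b` plus thresholds),
#' `ligand_rmsd` (`ligand`, `protein_fit`, `reference_frame`), `sasa`
#' (`target`, `context`, `probe_radius`, `n_sphere_points`), `heatmap`
#' (`residues`, `fit`), `link_prep` (`basis`, `cut_bonds`, `charges`,
#' `qm_selection`). Selections are named criteria lists as accepted by
#' [select_atoms()], or raw index vectors.
#'
#' @param path YAML file path.
#' @return the config list with the source text hash attached.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  attr(cfg, "config_hash") <- .fnv1a(paste(readLines(path, warn = FALSE), collapse = "\n"))
  cfg
}

.load_trajectory <- function(cfg, key = "trajectory") {
  p <- cfg[[key]]
  if (is.null(p)) stop("configuration error: no '", key, "' path configured")
  read_multimodel_pdb(p)
}

# Fail-fast resolution of every selection a profile run will touch.
.validate_profile_selections <- function(traj, cfg) {
  resolved <- list()
  resolve <- function(sel, what) {
    idx <- tryCatch(
      .resolve_selection(traj, sel, what),
      error = function(e) stop("configuration error in ", what, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    resolved[[what]] <<- idx
    idx
  }
  if (!is.null(cfg$ion)) {
    idx <- resolve(cfg$ion, "ion")
    if (length(idx) != 1L) stop("configuration error: ion selection must resolve to 1 atom")
    if (!is.null(cfg$rdf)) resolve(cfg$rdf$partners, "rdf.partners")
    if (!is.null(cfg$denticity)) resolve(cfg$denticity$oxygen_pair, "denticity.oxygen_pair")
  }
  for (i in seq_along(cfg$hbonds)) {
    hb <- cfg$hbonds[[i]]
    for (part in c("donor", "hydrogen", "acceptor")) {
      idx <- resolve(hb[[part]], paste0("hbonds[", i, "].", part))
      if (part != "acceptor" && length(idx) != 1L) {
        stop("configuration error: hbonds[", i, "].", part, " must resolve to 1 atom")
      }
      if (!length(idx)) {
        stop("configuration error: hbonds[", i, "].", part, " resolves to no atoms")
      }
    }
  }
  for (i in seq_along(cfg$distances)) {
    for (part in c("group_a", "group_b")) {
      idx <- resolve(cfg$distances[[i]][[part]], paste0("distances[", i, "].", part))
      if (!length(idx)) stop("configuration error: distances[", i, "].", part, " is empty")
    }
  }
  for (i in seq_along(cfg$stacking)) {
    for (part in c("ring_a", "ring_b")) {
      idx <- resolve(cfg$stacking[[i]][[part]], paste0("stacking[", i, "].", part))
      if (length(idx) < 3L) stop("configuration error: stacking[", i, "].", part,
                                 " needs >= 3 atoms")
    }
  }
  if (!is.null(cfg$ligand_rmsd)) {
    resolve(cfg$ligand_rmsd$ligand, "ligand_rmsd.ligand")
    resolve(cfg$ligand_rmsd$protein_fit, "ligand_rmsd.protein_fit")
  }
  if (!is.null(cfg$sasa)) {
    idx <- resolve(cfg$sasa$target, "sasa.target")
    if (!length(idx)) stop("configuration error: sasa.target is empty")
    if (!is.null(cfg$sasa$context)) resolve(cfg$sasa$context, "sasa.context")
  }
  resolved
}

.hb_criteria_from <- function(cfg) {
  hc <- cfg$hbond_criteria
  hbond_criteria(
    max_ha_distance = hc$max_ha_distance %||% 3.0,
    max_deviation_angle = hc$max_deviation_angle %||% 35,
    angle_vertex = hc$angle_vertex %||% "donor"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_log <- function(cfg, out_dir, seed) {
  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("zntraj %s", as.character(utils::packageVersion("zntraj"))),
    sprintf("config_hash %s", attr(cfg, "config_hash") %||% "unhashed"),
    sprintf("seed %s", seed),
    sprintf("inputs %s", paste(
      Filter(Negate(is.null), cfg[c("trajectory", "empty_trajectory")]),
      collapse = " "
    ))
  ), log_path)
  log_path
}

#' Run the full interaction-profile pipeline
#'
#' Executes every configured stage against the trajectory — ion RDF,
#' coordination number, denticity, hydrogen-bond occupancies, closest-atom
#' distance series, stacking classification, ligand RMSD, SASA — and writes
#' a machine-readable report (JSON + TSV contact table), per-stage series
#' files and a run log. All selections are resolved before any stage runs
#' (fail-fast); reruns of the same config and inputs are byte-identical.
#'
#' @param config config list from [read_analysis_config()], or a YAML path.
#' @return the report list (class `InteractionReport`), invisibly writing
#'   artifacts into `config$output_dir`.
#' @export
run_profile <- function(config) {
  cfg <- if (is.character(config)) read_analysis_config(config) else config
  traj <- .load_trajectory(cfg)
  sel <- .validate_profile_selections(traj, cfg)
  out_dir <- cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1
  report <- list(n_frames = n_frames(traj))

  if (!is.null(cfg$ion) && !is.null(cfg$rdf)) {
    rdf_cfg <- cfg$rdf
    prof <- compute_rdf(
      traj, sel$ion, sel$`rdf.partners`,
      bin_width = rdf_cfg$bin_width %||% 0.05,
      r_max = rdf_cfg$r_max %||% 10
    )
    export_rdf(prof, file.path(out_dir, "ion_rdf"),
               meta = list(seed = seed))
    cutoff <- rdf_cfg$cutoff %||%
      tryCatch(detect_first_minimum(prof), error = function(e) NA_real_)
    ion_section <- list(
      peak_position = if (any(prof$density > 0)) prof$bin_mid[which.max(prof$density)] else NA_real_,
      first_minimum = tryCatch(detect_first_minimum(prof), error = function(e) NA_real_),
      cutoff = cutoff
    )
    if (is.finite(cutoff)) {
      cn <- coordination_series(traj, sel$ion, sel$`rdf.partners`, cutoff,
                                bin_width = rdf_cfg$bin_width %||% 0.05,
                                r_max = rdf_cfg$r_max %||% 10)
      ion_section$mean_cn <- cn$mean_cn
    }
    if (!is.null(cfg$denticity)) {
      ion_section$denticity <- as.list(denticity_fractions(
        traj, sel$ion, sel$`denticity.oxygen_pair`,
        cutoff = cfg$denticity$cutoff %||% cutoff
      ))
    }
    report$ion <- ion_section
  }

  if (length(cfg$hbonds)) {
    crit <- .hb_criteria_from(cfg)
    rows <- lapply(seq_along(cfg$hbonds), function(i) {
      hb <- cfg$hbonds[[i]]
      triple <- hbond_triple(
        sel[[paste0("hbonds[", i, "].donor")]],
        sel[[paste0("hbonds[", i, "].hydrogen")]],
        sel[[paste0("hbonds[", i, "].acceptor")]]
      )
      st <- hbond_occupancy(traj, triple, crit)
      data.frame(
        residue = hb$label %||% paste0("contact_", i),
        group = hb$group %||% "",
        mean_distance = st$mean_distance,
        occupancy = st$occupancy,
        stringsAsFactors = FALSE
      )
    })
    contacts <- do.call(rbind, rows)
    write_contact_table(contacts, file.path(out_dir, "contacts.tsv"))
    report$contacts <- contacts
  }

  if (length(cfg$distances)) {
    report$distances <- lapply(seq_along(cfg$distances), function(i) {
      d <- cfg$distances[[i]]
      ds <- distance_series(
        traj,
        sel[[paste0("distances[", i, "].group_a")]],
        sel[[paste0("distances[", i, "].group_b")]]
      )
      label <- d$label %||% paste0("distance_", i)
      utils::write.table(
        data.frame(frame = seq_along(ds$series), distance = ds$series),
        file.path(out_dir, paste0(label, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      list(label = label, mean = ds$mean)
    })
  }

  if (length(cfg$stacking)) {
    report$stacking <- lapply(seq_along(cfg$stacking), function(i) {
      s <- cfg$stacking[[i]]
      fr <- stacking_fractions(
        traj,
        sel[[paste0("stacking[", i, "].ring_a")]],
        sel[[paste0("stacking[", i, "].ring_b")]],
        d_max = s$d_max %||% 6.5,
        theta_par = s$theta_par %||% 30,
        theta_perp = s$theta_perp %||% 60
      )
      c(list(label = s$label %||% paste0("rings_", i)), as.list(fr))
    })
  }

  if (!is.null(cfg$ligand_rmsd)) {
    series <- ligand_rmsd_series(
      traj, sel$`ligand_rmsd.ligand`, sel$`ligand_rmsd.protein_fit`,
      reference_frame = cfg$ligand_rmsd$reference_frame %||% 1L
    )
    utils::write.table(
      data.frame(frame = seq_along(series), rmsd = series),
      file.path(out_dir, "ligand_rmsd.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    report$ligand_rmsd <- list(mean = mean(series), max = max(series))
  }

  if (!is.null(cfg$sasa)) {
    sc <- sasa_config(
      probe_radius = cfg$sasa$probe_radius %||% 1.4,
      n_sphere_points = cfg$sasa$n_sphere_points %||% 960
    )
    res <- sasa_series(traj, sel$`sasa.target`,
                       sel$`sasa.context` %||% integer(0), config = sc)
    utils::write.table(
      data.frame(frame = seq_along(res$series), sasa = res$series),
      file.path(out_dir, "sasa.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    report$sasa <- res$summary[c("mean", "sd", "ci_half_width", "n", "level")]
  }

  .run_log(cfg, out_dir, seed)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  class(report) <- "InteractionReport"
  invisible(report)
}

#' @export
print.InteractionReport <- function(x, ...) {
  cat(sprintf("InteractionReport over %d frame(s)\n", x$n_frames))
  if (!is.null(x$ion)) {
    cat(sprintf("  ion: mean CN %.2f within %.2f A (peak %.2f A, first minimum %.2f A)\n",
                x$ion$mean_cn %||% NA, x$ion$cutoff, x$ion$peak_position,
                x$ion$first_minimum))
  }
  if (!is.null(x$contacts)) {
    for (i in seq_len(nrow(x$contacts))) {
      cat(sprintf("  contact %s: mean %.2f A, occupancy %.1f%%\n",
                  x$contacts$residue[i], x$contacts$mean_distance[i],
                  x$contacts$occupancy[i]))
    }
  }
  if (!is.null(x$sasa)) {
    cat(sprintf("  SASA: mean %.1f A^2 (+-%.1f, SD %.1f, n %d)\n",
                x$sasa$mean, x$sasa$ci_half_width, x$sasa$sd, x$sasa$n))
  }
  invisible(x)
}

#' Run the fluctuation-corrected heatmap pipeline
#'
#' Needs `trajectory` (loaded) and `empty_trajectory` in the config. Writes
#' the raw loaded-vs-apo matrix, the apo self-comparison matrix, the
#' per-residue baseline and the corrected matrix as TSV.
#'
#' @param config config list or YAML path.
#' @return the `CorrectedHeatmap`, invisibly.
#' @export
run_heatmap <- function(config) {
  cfg <- if (is.character(config)) read_analysis_config(config) else config
  if (is.null(cfg$empty_trajectory)) {
    stop("configuration error: heatmap needs an 'empty_trajectory'")
  }
  loaded_traj <- .load_trajectory(cfg, "trajectory")
  empty_traj <- .load_trajectory(cfg, "empty_trajectory")
  out_dir <- cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  residues <- cfg$heatmap$residues %||% NULL
  loaded <- per_residue_rmsd(loaded_traj, empty_traj, residues = residues)
  empty_self <- per_residue_rmsd(empty_traj, empty_traj, residues = residues)
  hm <- corrected_heatmap(loaded, empty_self)
  write_heatmap_matrix(loaded, file.path(out_dir, "per_residue_rmsd_raw.tsv"))
  write_heatmap_matrix(empty_self, file.path(out_dir, "per_residue_rmsd_empty_self.tsv"))
  utils::write.table(
    data.frame(residue = names(hm$baseline), baseline = hm$baseline),
    file.path(out_dir, "baseline.tsv"), sep = "\t", row.names = FALSE, quote = FALSE
  )
  write_heatmap_matrix(hm, file.path(out_dir, "per_residue_rmsd_corrected.tsv"))
  .run_log(cfg, out_dir, cfg$seed %||% 1)
  invisible(hm)
}

#' Run QM/MM boundary preparation
#'
#' Places a link atom for every configured cut bond (per its residue type and
#' the configured basis) and writes the charge-scaled embedding point-charge
#' file. Cut bonds are given as a list of `residue_type` plus `c_alpha` /
#' `c_beta` selections (each resolving to one atom); raw charges as a numeric
#' vector (one per MM atom) or a whitespace-delimited file of charges.
#'
#' @param config config list or YAML path.
#' @return list with `link_atoms` (data.frame) and `charges`
#'   (`PointChargeSet`), invisibly.
#' @export
run_link_prep <- function(config) {
  cfg <- if (is.character(config)) read_analysis_config(config) else config
  lp <- cfg$link_prep
  if (is.null(lp)) stop("configuration error: no link_prep section")
  traj <- .load_trajectory(cfg)
  frame <- traj$frames[[lp$frame %||% 1L]]
  basis <- lp$basis %||% "TZ"
  out_dir <- cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  links <- lapply(seq_along(lp$cut_bonds), function(i) {
    cb <- lp$cut_bonds[[i]]
    params <- lookup_link_params(cb$residue_type, basis)
    ia <- .resolve_selection(traj, cb$c_alpha, paste0("cut_bonds[", i, "].c_alpha"))
    ib <- .resolve_selection(traj, cb$c_beta, paste0("cut_bonds[", i, "].c_beta"))
    if (length(ia) != 1L || length(ib) != 1L) {
      stop("configuration error: cut_bonds[", i, "] endpoints must each resolve to 1 atom")
    }
    pos <- place_link_atom(frame[ia, ], frame[ib, ], params$rho)
    data.frame(
      bond = i, residue_type = cb$residue_type, basis = basis,
      rho = params$rho, x = pos[1], y = pos[2], z = pos[3]
    )
  })
  link_atoms <- do.call(rbind, links)
  if (!is.null(link_atoms)) {
    utils::write.table(link_atoms, file.path(out_dir, "link_atoms.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  charges <- NULL
  if (!is.null(lp$charges)) {
    raw <- if (is.character(lp$charges)) scan(lp$charges, quiet = TRUE) else as.numeric(lp$charges)
    qm_idx <- if (!is.null(lp$qm_selection)) {
      .resolve_selection(traj, lp$qm_selection, "link_prep.qm_selection")
    } else integer(0)
    mm_atoms <- seq_len(nrow(traj$topology))
    ec <- embedding_config(
      scale_factor = lp$scale_factor %||% 0.666,
      qm_selection = qm_idx
    )
    charges <- export_embedding_charges(
      frame, mm_atoms, raw, ec, path = file.path(out_dir, "embedding_charges.dat")
    )
  }
  .run_log(cfg, out_dir, cfg$seed %||% 1)
  invisible(list(link_atoms = link_atoms, charges = charges))
}
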