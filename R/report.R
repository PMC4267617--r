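# Run configuration and the one-shot report bundle: CDF/RDF/charge
# profiles, occupancy tables (by sequence and by atom type), residence
# times, binding distances, pockets and diffusion summaries, written as
# TSV files with '#'-prefixed metadata headers plus a JSON manifest.
# Reporting units: times ns, distances A, occupancies percent.

RUN_CONFIG_KEYS <- c("input", "species", "cutoffs", "window", "bins",
                     "axis", "seed", "outdir", "residence", "diffusion",
                     "simulate")

#' Validate a run configuration
#'
#' Unknown keys are rejected before any computation.
#'
#' @param config named list (or path handled by the CLI); recognised keys:
#'   `input` (`path`, `dialect`, or a `trajectory` object), `species`
#'   (labels to analyse), `cutoffs` (named overrides, A), `window`
#'   (`c(t0, t1)` ps), `bins` (`r_max`, `dr_cdf`, `dr_rdf`), `axis`
#'   (`pyrimidine_ref`, `trim_ends`, `axial`), `seed`, `outdir`,
#'   `residence` (`lag_min`, `lag_max`, `lag_step`), `diffusion`
#'   (`max_lag`), `simulate` (generator spec for the CLI).
#' @return validated config of class `RunConfig`.
#' @export
run_config <- function(config) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  config$bins <- modifyList(list(r_max = 30, dr_cdf = 0.5, dr_rdf = 0.1),
                            config$bins %||% list())
  config$axis <- modifyList(list(pyrimidine_ref = "N4", trim_ends = 0,
                                 axial = "duplex"), config$axis %||% list())
  config$residence <- modifyList(list(lag_min = 10, lag_max = 1000,
                                      lag_step = 10),
                                 config$residence %||% list())
  config$diffusion <- modifyList(list(max_lag = 100), config$diffusion %||% list())
  if (!is.null(config$species) && !length(config$species)) {
    stop("species selection is empty")
  }
  structure(config, class = "RunConfig")
}

#' Write a data frame as a report TSV
#'
#' '#'-prefixed metadata header lines followed by a tab-separated table.
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta named character/numeric vector written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, meta = c()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(paste0("# ", k, ": ", meta[[k]]), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) formatC(col, digits = 8, format = "g") else as.character(col)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

profile_df <- function(d) {
  data.frame(bin_left = head(d$bin_edges, -1), bin_right = tail(d$bin_edges, -1),
             value = d$values, stderr = d$stderr %||% NA_real_,
             raw_count = d$raw_counts)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), c("input", "outdir"))], f)
  unname(tools::md5sum(f))
}

resolve_trajectory <- function(config) {
  inp <- config$input
  if (is.null(inp)) stop("config$input is required")
  if (!is.null(inp$trajectory)) return(inp$trajectory)
  if (is.null(inp$path)) stop("config$input needs a 'path' or 'trajectory'")
  load_structure(inp$path, dialect = inp$dialect %||% "pdb_multimodel")
}

#' Run the full analysis report
#'
#' One invocation computes and writes the configured stages; any stage
#' failure aborts with the stage name and removes partial outputs.
#' Identical config + seed yields byte-identical outputs.
#'
#' @param config a [run_config()] (or plain list).
#' @param stages subset of stages to run.
#' @return invisible named list of written file paths (the manifest
#'   records versions, seed and a config hash).
#' @export
run_report <- function(config,
                       stages = c("cdf", "rdf", "charge", "occupancy",
                                  "residence", "bindstats", "pockets",
                                  "structure", "diffusion")) {
  config <- run_config(unclass(config))
  stages <- match.arg(stages, several.ok = TRUE)
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  traj <- resolve_trajectory(config)
  set.seed(config$seed)
  species <- config$species %||% names(traj$species)
  if (!length(species)) stop("no ion species to analyse")
  window <- config$window
  cutoff_for <- function(sp) {
    cf <- unlist(config$cutoffs)[sp]
    if (is.null(cf) || is.na(cf)) default_cutoff(sp) else unname(cf)
  }
  has_duplex <- any(!is.na(traj$topology$atoms$base)) &&
    !is.null(traj$topology$pairing)
  written <- character(0)
  emit <- function(df, name, meta) {
    p <- file.path(outdir, name)
    write_report_tsv(df, p, meta)
    written <<- c(written, p)
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  hf <- NULL
  if (has_duplex) {
    hf <- run_stage("axis", function() {
      helix_frames(traj, pyrimidine_ref = config$axis$pyrimidine_ref,
                   trim_ends = config$axis$trim_ends)
    })
  }
  base_meta <- c(package = paste0("ionscape ", utils::packageVersion("ionscape")),
                 seed = config$seed, config = config_hash(config))
  regions <- c("major", "minor", "backbone_Oprime", "phosphate")
  if ("cdf" %in% stages && has_duplex) run_stage("cdf", function() {
    for (sp in species) {
      d <- compute_cdf(traj, sp, hf, r_max = config$bins$r_max,
                       dr = config$bins$dr_cdf, window = window,
                       axial = config$axis$axial)
      emit(profile_df(d), paste0("cdf_", gsub("[^A-Za-z0-9]", "", sp), ".tsv"),
           c(base_meta, kind = "cdf", species = sp, units = "mol/L vs A"))
    }
  })
  if ("rdf" %in% stages && has_duplex) run_stage("rdf", function() {
    for (sp in species) {
      for (reg in regions) {
        sites <- select_atoms(traj$topology, region = reg)
        if (!length(sites)) next
        d <- compute_rdf(traj, sp, sites, r_max = min(10, config$bins$r_max),
                         dr = config$bins$dr_rdf, window = window)
        emit(profile_df(d),
             paste0("rdf_", gsub("[^A-Za-z0-9]", "", sp), "_", reg, ".tsv"),
             c(base_meta, kind = "rdf", species = sp, region = reg))
      }
    }
  })
  if ("charge" %in% stages && has_duplex) run_stage("charge", function() {
    d <- charge_accumulation(traj, hf, r_max = config$bins$r_max,
                             dr = config$bins$dr_cdf, window = window,
                             axial = config$axis$axial)
    emit(profile_df(d), "charge_accumulation.tsv",
         c(base_meta, kind = "charge",
           net_charge = traj$topology$net_charge))
  })
  if ("occupancy" %in% stages && has_duplex) run_stage("occupancy", function() {
    for (sp in species) {
      for (mode in c("direct", "mediated")) {
        cut <- if (mode == "direct") cutoff_for(sp) else 6.0
        tab <- occupancy_by_sequence(traj, sp, cutoff = cut, window = window)
        emit(tab, paste0("occupancy_seq_", gsub("[^A-Za-z0-9]", "", sp),
                         "_", mode, ".tsv"),
             c(base_meta, species = sp, cutoff_A = cut,
               note = "second strand reported 5'->3' (reverse spatial order)"))
      }
      emit(atom_occupancy_table(traj, sp, cutoff_for(sp), window),
           paste0("occupancy_atom_", gsub("[^A-Za-z0-9]", "", sp), ".tsv"),
           c(base_meta, species = sp, cutoff_A = cutoff_for(sp)))
    }
  })
  if ("residence" %in% stages) run_stage("residence", function() {
    rows <- list()
    at <- if (has_duplex) {
      atom_types(traj$topology)
    } else {
      # non-duplex systems (e.g. a telegraph fixture): every atom that is
      # not itself a mobile species is a candidate site
      a <- traj$topology$atoms
      free <- setdiff(seq_len(nrow(a)), unlist(traj$species))
      if (!length(free)) stop("no candidate site atoms")
      data.frame(name = a$name[free], base = NA_character_,
                 region = "site", index = free)
    }
    for (sp in species) {
      for (i in seq_len(nrow(at))) {
        sel <- if (has_duplex) {
          select_atoms(traj$topology, name = at$name[i], base = at$base[i])
        } else at$index[i]
        tr <- occupancy_trace(traj, sel, sp, cutoff = cutoff_for(sp),
                              window = window)
        if (sum(tr$p) == 0) next
        rr <- residence_time(tr, config$residence$lag_min,
                             config$residence$lag_max, config$residence$lag_step)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, atom = at$name[i], base = at$base[i],
          region = at$region[i],
          tau_R_ns = if (rr$censored) NA_real_ else rr$tau_R,
          censored = rr$censored, fit_r2 = rr$fit_r2,
          occupancy_pct = occupancy_fraction(tr))
      }
    }
    emit(if (length(rows)) do.call(rbind, rows) else
           data.frame(species = character(), atom = character()),
         "residence_times.tsv", c(base_meta, units = "ns"))
  })
  if ("bindstats" %in% stages && has_duplex) run_stage("bindstats", function() {
    rows <- list()
    a <- traj$topology$atoms
    for (sp in species) {
      at <- atom_types(traj$topology)
      for (i in seq_len(nrow(at))) {
        sel <- select_atoms(traj$topology, name = at$name[i], base = at$base[i])
        for (s in sel) {
          bs <- binding_distance_stats(traj, s, sp, cutoff = cutoff_for(sp),
                                       window = window)
          if (bs$undefined) next
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, atom = at$name[i], base = at$base[i],
            residue = a$residue[s], chain = a$chain[s],
            mean_A = bs$mean, sd_A = bs$sd, n_bound = bs$n_bound_frames)
        }
      }
    }
    emit(if (length(rows)) do.call(rbind, rows) else
           data.frame(species = character()),
         "binding_distances.tsv", c(base_meta, units = "A"))
  })
  if ("pockets" %in% stages && has_duplex) run_stage("pockets", function() {
    rows <- list()
    for (sp in species) {
      pk <- detect_pockets(traj, sp, cutoff = cutoff_for(sp), window = window)
      for (p in pk) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, ion_atom = p$ion, members = p$member_names,
          n_members = length(p$members), dwell_ns = p$dwell / 1000)
      }
    }
    emit(if (length(rows)) do.call(rbind, rows) else
           data.frame(species = character()),
         "pockets.tsv", c(base_meta, units = "ns"))
  })
  if ("structure" %in% stages && has_duplex) run_stage("structure", function() {
    emit(structure_table(traj, frames = traj$n_frames), "structure_metrics.tsv",
         c(base_meta, frame = traj$n_frames))
  })
  if ("diffusion" %in% stages) run_stage("diffusion", function() {
    rows <- list()
    for (sp in species) {
      un <- unwrap_coordinates(traj, sp)
      max_lag <- min(config$diffusion$max_lag,
                     traj$dt * floor((traj$n_frames - 1) / 5))
      if (max_lag < 25 * traj$dt) next  # need >= 10 lag points in the fit window
      m <- msd(un, traj$dt, max_lag)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, D_A2_ps = m$D, D_cm2_s = m$D_cm2_s,
        fit_lo_ps = m$fit_window[1], fit_hi_ps = m$fit_window[2],
        fit_r2 = m$fit_r2, flagged = m$fit_flagged)
    }
    emit(if (length(rows)) do.call(rbind, rows) else
           data.frame(species = character()),
         "diffusion.tsv", c(base_meta, units = "A^2/ps"))
  })
  manifest <- list(package = "ionscape",
                   version = as.character(utils::packageVersion("ionscape")),
                   seed = config$seed, config_hash = config_hash(config),
                   files = basename(written))
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, mf))
}

# distinct (name, base) duplex atom types with their region label
atom_types <- function(top) {
  a <- top$atoms[!is.na(top$atoms$base), ]
  at <- unique(a[, c("name", "base")])
  at$region <- classify_region(at$name, at$base)
  at <- at[at$name != "P" & !startsWith(at$name, "C"), ]
  rownames(at) <- NULL
  at
}

# per-atom-type occupancy averaged over the duplex (direct + mediated)
atom_occupancy_table <- function(traj, species, cutoff, window) {
  at <- atom_types(traj$topology)
  a <- traj$topology$atoms
  rows <- lapply(seq_len(nrow(at)), function(i) {
    sel <- select_atoms(traj$topology, name = at$name[i], base = at$base[i])
    per_atom <- vapply(sel, function(s) {
      occupancy_fraction(occupancy_trace(traj, s, species, cutoff, window))
    }, 0)
    per_atom6 <- vapply(sel, function(s) {
      occupancy_fraction(occupancy_trace(traj, s, species, 6.0, window))
    }, 0)
    data.frame(atom = at$name[i], base = at$base[i], region = at$region[i],
               occupancy_direct = mean(per_atom),
               occupancy_mediated = mean(per_atom6))
  })
  do.call(rbind, rows)
}
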