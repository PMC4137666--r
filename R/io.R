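# File formats: multi-model PDB ensembles (via bio3d), delimited
# observable tables, and the structured pipeline configuration.

#' Write a structure or ensemble as a (multi-model) PDB file
#'
#' Coordinates are written at the standard PDB precision of 3 decimals;
#' ensembles become MODEL/ENDMDL blocks sharing one topology.
#'
#' @param x a `cc_structure` or `cc_ensemble`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure_ensemble <- function(x, file) {
  if (inherits(x, "cc_structure")) x <- new_ensemble(x$atoms, list(x$xyz))
  stopifnot(inherits(x, "cc_ensemble"))
  xyz <- do.call(rbind, lapply(x$xyz, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = x$atoms$resno, resid = x$atoms$resid,
                   eleno = x$atoms$eleno, elety = x$atoms$elety,
                   chain = x$atoms$chain)
  invisible(file)
}

#' Read a (multi-model) PDB file as an ensemble
#'
#' Parses fixed-column PDB ATOM records (via bio3d), returning a one-frame
#' ensemble for single-model files. Models with inconsistent atom counts
#' are rejected with the offending model named.
#'
#' @param path PDB file with a single model or MODEL/ENDMDL blocks.
#' @return a `cc_ensemble`.
#' @export
read_structure_ensemble <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM|HETATM)", lines[s:e])), model_starts, ends)
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop("model ", bad, " has ", counts[bad],
           " atoms but model 1 has ", counts[1], call. = FALSE)
    }
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(eleno = p$atom$eleno, elety = p$atom$elety,
                      resid = p$atom$resid, chain = p$atom$chain,
                      resno = p$atom$resno, stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nrow(p$xyz)), function(i)
    matrix(p$xyz[i, ], ncol = 3, byrow = TRUE))
  new_ensemble(atoms, frames)
}

#' Write per-frame observable tables
#'
#' One tab-separated file per ladder temperature, named
#' `replica_<temperature>K.tsv`, with columns `temperature_K`, `frame`,
#' `energy_kJmol` (when present) and one column per remaining observable.
#'
#' @param series a `cc_replica_series`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_observable_tables <- function(series, dir) {
  frames <- if (is.data.frame(series)) series else series$frames
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- as.data.frame(frames)
  names(df)[names(df) == "temperature"] <- "temperature_K"
  names(df)[names(df) == "energy"] <- "energy_kJmol"
  for (tt in unique(df$temperature_K)) {
    sub <- df[df$temperature_K == tt, ]
    f <- file.path(dir, sprintf("replica_%08.2fK.tsv", tt))
    write.table(sub, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read per-frame observable tables
#'
#' Reads every `*.tsv` file in a directory (as written by
#' [write_observable_tables()]), checks for duplicate (temperature, frame)
#' rows and non-numeric cells, and returns a `cc_replica_series` without
#' coordinates. A missing energy column is allowed; [wham_reweight()] will
#' then refuse with an explanatory error.
#'
#' @param dir directory of delimited observable tables.
#' @return a `cc_replica_series`.
#' @export
read_observable_tables <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv tables found in ", dir, call. = FALSE)
  parts <- lapply(files, function(f) {
    df <- read.delim(f, check.names = FALSE)
    if (!all(c("temperature_K", "frame") %in% names(df)))
      stop("table ", f, " lacks temperature_K/frame columns", call. = FALSE)
    num <- vapply(df, is.numeric, logical(1))
    if (!all(num[setdiff(names(df), "associated")]))
      stop("non-numeric cells in ", f, " (columns: ",
           paste(names(df)[!num], collapse = ", "), ")", call. = FALSE)
    df
  })
  df <- do.call(rbind, parts)
  key <- paste(df$temperature_K, df$frame)
  if (anyDuplicated(key))
    stop("duplicate (temperature, frame) rows: ",
         key[duplicated(key)][1], call. = FALSE)
  names(df)[names(df) == "temperature_K"] <- "temperature"
  names(df)[names(df) == "energy_kJmol"] <- "energy"
  df <- df[order(df$temperature, df$frame), ]
  structure(list(frames = tibble::as_tibble(df),
                 temperatures = sort(unique(df$temperature)),
                 ensembles = NULL),
            class = "cc_replica_series")
}

#' Default pipeline configuration
#'
#' All numeric constants of the analysis live here: geometric cutoffs
#' (hydrogen bond 3.5 A and 30 degrees, salt bridge 4.0 A, hydrophobic
#' contact 7.0 A), the hydrophobic set and pKa table, the two pH
#' conditions, the replica ladder, the two-state melting model, the
#' trailing analysis window, clustering and WHAM settings. Every value can
#' be overridden before [run_pipeline()].
#'
#' @param sequence amino-acid sequence of the monomer.
#' @param seed integer seed forwarded to the melting model.
#' @return nested configuration list.
#' @export
default_config <- function(sequence = strrep("IAAEKQL", 4), seed = 1) {
  list(
    sequence = sequence,
    crick = list(supercoil_radius_R0 = 6.1, registry_offset = 0),
    cutoffs = list(hbond_d = 3.5, hbond_a = 30, salt_d = 4.0,
                   hydroph_d = 7.0),
    hydrophobic_set = hydrophobic_residues,
    pka_table = as.list(default_pka_table),
    ph = c(1.6, 7.4),
    ladder = list(t_min = 303.15, t_max = 809.57, n = 16),
    model = list(tm_association = 450, tm_helix = 550,
                 width_association = 20, width_helix = 20,
                 frames_per_temperature = 40,
                 energy_scale_helix = 2, energy_scale_contact = 1,
                 noise_sd = 5),
    window_fraction = 0.5,
    cluster = list(top_n = 400, rms_cutoff = 3.0),
    wham = list(e_bins = 120, xy_bins = c(40, 40), tol = 1e-7,
                max_iter = 10000, t0 = 303.15),
    seed = seed
  )
}

#' Read a pipeline configuration file
#'
#' YAML configuration with the same nesting as [default_config()]; values
#' present in the file override the defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  # YAML 1.1 would resolve bare y/n/yes/no scalars (such as the ladder key
  # "n") to booleans; keep them literal and only honour true/false/on/off
  handlers <- list(
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "on")) TRUE else x,
    "bool#no" = function(x) if (tolower(x) %in% c("false", "off")) FALSE
                            else x)
  user <- yaml::read_yaml(path, handlers = handlers)
  utils::modifyList(default_config(), user)
}

require_keys <- function(config, keys) {
  for (k in keys)
    if (is.null(config[[k]]))
      stop("config is missing required key: ", k, call. = FALSE)
}

#' Per-frame interaction census of stored replica ensembles
#'
#' Runs the full geometric interaction census (hydrogen bonds by class,
#' salt bridges, hydrophobic contacts, helix content) on every stored
#' frame of a replica series generated with `store_coords = TRUE`.
#'
#' @param series a `cc_replica_series` with `ensembles`.
#' @param protonation a single-chain [assign_protonation()] state applied
#'   to all chains (NULL = neutral pH 7.4).
#' @param cutoffs list with `hbond_d`, `hbond_a`, `salt_d`, `hydroph_d`.
#' @param hydrophobic_set residues counted as hydrophobic.
#' @return tibble with one row per frame: temperature, frame, energy,
#'   intermonomer_hbonds, mainchain_hbonds, salt_bridges,
#'   hydrophobic_contacts, helix_content.
#' @export
census_ensembles <- function(series, protonation = NULL,
                             cutoffs = list(hbond_d = 3.5, hbond_a = 30,
                                            salt_d = 4.0, hydroph_d = 7.0),
                             hydrophobic_set = hydrophobic_residues) {
  stopifnot(inherits(series, "cc_replica_series"))
  if (is.null(series$ensembles))
    stop("series has no stored coordinates; regenerate with ",
         "store_coords = TRUE", call. = FALSE)
  rows <- list()
  for (ti in seq_along(series$temperatures)) {
    ens <- series$ensembles[[ti]]
    tt <- series$temperatures[ti]
    sub <- series$frames[series$frames$temperature == tt, ]
    for (f in seq_len(n_frames(ens))) {
      st <- get_frame(ens, f)
      hb <- classify_and_count(detect_hbonds(st, cutoffs$hbond_d,
                                             cutoffs$hbond_a, protonation))
      n_of <- function(kind, cls) {
        v <- hb$n[hb$kind == kind & hb$class == cls]
        if (length(v)) sum(v) else 0L
      }
      sb <- detect_salt_bridges(st, protonation, cutoffs$salt_d)
      hc <- detect_hydrophobic_contacts(st, hydrophobic_set,
                                        cutoffs$hydroph_d)
      rows[[length(rows) + 1]] <- tibble::tibble(
        temperature = tt, frame = f,
        energy = sub$energy[sub$frame == f],
        intermonomer_hbonds = n_of("hbond", "intermonomer"),
        mainchain_hbonds = n_of("hbond", "mainchain"),
        salt_bridges = nrow(sb),
        hydrophobic_contacts = nrow(hc),
        helix_content = assign_helix(st)$content)
    }
  }
  do.call(rbind, rows)
}

#' Run the full stability-analysis pipeline on synthetic data
#'
#' End-to-end run: build the ideal trimer, generate replica ensembles over
#' the ladder, census interactions at both pH conditions, average the
#' observables over the trailing window, extract melting temperatures (or
#' midpoints for non-sigmoidal curves), reconstruct the WHAM surface over
#' (helix content, hydrophobic contacts as percent of the folded
#' reference) and locate its basins. Identical configuration and seed
#' reproduce the report exactly.
#'
#' @param config configuration list as from [default_config()].
#' @param out_dir optional directory; when given, observable tables, the
#'   Tm report, the surface and a run log with every effective parameter
#'   are written there.
#' @return list with `structure`, `series`, `census` (per pH), `curves`,
#'   `tm_table`, `surface`, `basins`, and `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  require_keys(config, c("sequence", "crick", "cutoffs", "hydrophobic_set",
                         "pka_table", "ph", "ladder", "model",
                         "window_fraction", "wham", "seed"))
  params <- crick_parameters(
    supercoil_radius_R0 = config$crick$supercoil_radius_R0,
    registry_offset = config$crick$registry_offset %||% 0)
  folded <- build_ideal_coiled_coil(config$sequence, params)
  ladder <- make_ladder(config$ladder$t_min, config$ladder$t_max,
                        config$ladder$n)
  model <- do.call(melting_model, c(config$model, list(seed = config$seed)))
  series <- generate_replica_ensembles(
    folded, ladder, model, store_coords = TRUE,
    hydrophobic_set = config$hydrophobic_set,
    contact_cutoff = config$cutoffs$hydroph_d)

  seq1 <- structure_sequence(folded)[[1]]
  pka <- unlist(config$pka_table)
  census <- lapply(config$ph, function(ph) {
    census_ensembles(series,
                     protonation = assign_protonation(seq1, ph, pka),
                     cutoffs = config$cutoffs,
                     hydrophobic_set = config$hydrophobic_set)
  })
  names(census) <- paste0("pH_", config$ph)

  obs <- c("intermonomer_hbonds", "mainchain_hbonds", "salt_bridges",
           "hydrophobic_contacts", "helix_content")
  curves <- lapply(census, function(cen)
    ensemble_averages(cen, obs, config$window_fraction))

  tm_rows <- list()
  for (ph_name in names(curves)) {
    for (ob in obs) {
      cur <- curves[[ph_name]][[ob]]
      tmres <- extract_tm(cur)
      mid <- if (max(cur$mean) > min(cur$mean))
        extract_midpoint(cur) else NA_real_
      tm_rows[[length(tm_rows) + 1]] <- tibble::tibble(
        condition = ph_name, observable = ob, tm = tmres$tm,
        diagnostic = tmres$diagnostic, midpoint = mid,
        reported = if (tmres$diagnostic == "sigmoidal") tmres$tm else mid)
    }
  }
  tm_table <- do.call(rbind, tm_rows)

  neutral <- census[[which.max(config$ph)]]
  neutral$contacts_pct <- 100 * neutral$hydrophobic_contacts /
    max(1L, series$folded_contacts)
  surface <- wham_reweight(neutral,
                           coords = c("helix_content", "contacts_pct"),
                           t0 = config$wham$t0,
                           e_bins = config$wham$e_bins,
                           xy_bins = config$wham$xy_bins,
                           tol = config$wham$tol,
                           max_iter = config$wham$max_iter,
                           window_fraction = config$window_fraction)
  basins <- find_basins(surface)

  result <- list(structure = folded, series = series, census = census,
                 curves = curves, tm_table = tm_table, surface = surface,
                 basins = basins, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_structure_ensemble(result$structure,
                           file.path(out_dir, "folded_model.pdb"))
  for (ph_name in names(result$census))
    write_observable_tables(result$census[[ph_name]],
                            file.path(out_dir, paste0("tables_", ph_name)))
  write.table(as.data.frame(result$tm_table),
              file.path(out_dir, "tm_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- result$surface
  grid <- expand.grid(seq_along(s$x_centers), seq_along(s$y_centers))
  surf_df <- data.frame(bin_x_center = s$x_centers[grid[, 1]],
                        bin_y_center = s$y_centers[grid[, 2]],
                        probability = s$prob[as.matrix(grid)],
                        free_energy_kJmol = s$free_energy[as.matrix(grid)])
  write.table(surf_df, file.path(out_dir, "wham_surface.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(
    "# coilstab pipeline run: effective configuration",
    paste0("seed: ", result$config$seed),
    yaml::as.yaml(result$config[setdiff(names(result$config), "seed")]))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
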