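#' Read and write structures as PDB
#'
#' Structure tibbles are mapped onto PDB records with one atom per site:
#' receptor sites on chain A, ligand sites on chain B, consecutive residue
#' numbers within each chain.  `write_structure()` accepts a single
#' structure or a list (written as a multi-model file); per-model annotation
#' values can be stored in the occupancy and B-factor fields (the package's
#' path exports store lambda and the window id there).  `read_structure()`
#' parses a (multi-model) PDB back into a list of structure tibbles; for
#' records with alternate locations only the first altloc is kept (with a
#' message).  Coordinates survive a round trip to PDB precision (1e-3 A).
#'
#' @param structures a structure tibble or a list of them (models).
#' @param file path of the PDB file.
#' @param occupancy,bfactor optional per-model annotation values.
#' @param radius default site radius assigned on read.
#' @return `read_structure()`: a list of structure tibbles with attribute
#'   `occupancy` (per-model values); `write_structure()`: the file path,
#'   invisibly.
#' @name structure_io
NULL

#' @rdname structure_io
#' @export
write_structure <- function(structures, file, occupancy = NULL,
                            bfactor = NULL) {
  if (is_tibble(structures) || is.data.frame(structures)) {
    structures <- list(structures)
  }
  n_mod <- length(structures)
  occupancy <- occupancy %||% rep(1, n_mod)
  bfactor <- bfactor %||% rep(0, n_mod)
  con <- file(file, "w")
  on.exit(close(con))
  for (m in seq_len(n_mod)) {
    st <- structures[[m]]
    chain <- ifelse(st$role == "ligand", "B", "A")
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = tmp, xyz = as.vector(t(as.matrix(st[, c("x", "y", "z")]))),
                     resno = st$seq, chain = chain,
                     resid = rep("BEA", nrow(st)),
                     elety = rep("CA", nrow(st)),
                     o = rep(occupancy[m], nrow(st)),
                     b = rep(bfactor[m], nrow(st)))
    lines <- readLines(tmp)
    unlink(tmp)
    lines <- lines[grepl("^ATOM|^HETATM", lines)]
    if (n_mod > 1) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(lines, con)
    if (n_mod > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' @rdname structure_io
#' @export
read_structure <- function(file, radius = 1.25) {
  if (!file.exists(file)) abort(paste0("file not found: ", file))
  pdb <- tryCatch(bio3d::read.pdb(file, multi = TRUE, verbose = FALSE),
                  error = function(e) {
                    abort(paste0("unparseable PDB '", file, "': ",
                                 conditionMessage(e)))
                  })
  at <- pdb$atom
  if (any(!is.na(at$alt) & at$alt != "")) {
    first_alt <- !duplicated(paste(at$chain, at$resno, at$elety)) |
      is.na(at$alt) | at$alt %in% c("", "A")
    if (!all(first_alt)) {
      inform("alternate locations present: keeping the first altloc")
      at <- at[first_alt, ]
    }
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_mod <- nrow(xyz)
  occ <- scan_model_occupancy(file, n_mod)
  models <- purrr::map(seq_len(n_mod), function(m) {
    xm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    tibble(site = paste0(at$chain, at$resno),
           role = ifelse(at$chain == "B", "ligand", "receptor"),
           seq = at$resno, x = xm[, 1], y = xm[, 2], z = xm[, 3],
           radius = radius)
  })
  attr(models, "occupancy") <- occ
  models
}

# per-model occupancy values (first ATOM record of each MODEL block)
scan_model_occupancy <- function(file, n_mod) {
  lines <- readLines(file)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) starts <- 0
  is_atom <- grepl("^ATOM|^HETATM", lines)
  vapply(starts, function(s) {
    at <- lines[which(is_atom & seq_along(lines) > s)[1]]
    as.numeric(substr(at, 55, 60))
  }, numeric(1))
}

#' Ensemble table serialization
#'
#' Writes/reads the per-snapshot ensemble container as CSV with a JSON
#' metadata sidecar (`<file>.json`) holding the provenance needed to re-run
#' reweighting: config hash, seeds, bias description and temperature window.
#'
#' @param ensemble ensemble tibble.
#' @param file CSV path.
#' @param metadata named list stored in the JSON sidecar.
#' @return `read_ensemble()`: the tibble with attribute `metadata`.
#' @name ensemble_io
NULL

#' @rdname ensemble_io
#' @export
write_ensemble <- function(ensemble, file, metadata = list()) {
  if (any(!is.finite(ensemble$energy))) abort("non-finite energies in ensemble")
  write.csv(as.data.frame(ensemble), file, row.names = FALSE)
  jsonlite::write_json(metadata, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname ensemble_io
#' @export
read_ensemble <- function(file) {
  if (!file.exists(file)) abort(paste0("file not found: ", file))
  out <- as_tibble(read.csv(file))
  meta_path <- paste0(file, ".json")
  if (file.exists(meta_path)) {
    attr(out, "metadata") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  out
}

#' Bias serialization
#'
#' The bias grid (energy, bias, effective temperature) goes to CSV, the full
#' reconstruction data (polynomial coefficients, window, degree, iteration)
#' to a JSON sidecar.
#'
#' @param bias an `mcmd_bias`.
#' @param file CSV path (sidecar at `<file>.json`).
#' @return `read_bias()`: the reconstructed `mcmd_bias`.
#' @name bias_io
NULL

#' @rdname bias_io
#' @export
write_bias <- function(bias, file) {
  write.csv(as.data.frame(tidy(bias)), file, row.names = FALSE)
  jsonlite::write_json(
    list(coef = bias$coef, grid_e = bias$grid$e, grid_b = bias$grid$b,
         lnn_coef = bias$lnn_coef, emin = bias$emin,
         emax = bias$emax, window = bias$window, t_sim = bias$t_sim,
         degree = bias$degree, iteration = bias$iteration,
         max_scale = bias$max_scale),
    paste0(file, ".json"), digits = NA)
  invisible(file)
}

#' @rdname bias_io
#' @export
read_bias <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  grid <- if (!is.null(meta$grid_e)) tibble(e = meta$grid_e, b = meta$grid_b)
  mcmd_bias(coef = meta$coef, grid = grid, emin = meta$emin, emax = meta$emax,
            window = meta$window, t_sim = meta$t_sim,
            lnn_coef = meta$lnn_coef, degree = meta$degree,
            iteration = meta$iteration,
            max_scale = meta$max_scale %||% 10)
}

#' Run configuration
#'
#' A run configuration collects every stage parameter of the pipeline in one
#' serializable list; re-running with an identical configuration reproduces
#' identical outputs for all deterministic stages.  The provenance stamp
#' `config_hash()` is embedded in report files, and mixed-hash artifacts are
#' refused by [write_report()].
#'
#' @param ... named stage parameters (any nesting of lists and atomic
#'   values).
#' @param file YAML path.
#' @param config a `run_config`.
#' @return `run_config()` an object of class `run_config`;
#'   `config_hash()` a character hash.
#' @name run_config
NULL

#' @rdname run_config
#' @export
run_config <- function(...) {
  structure(list(...), class = "run_config")
}

#' @rdname run_config
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

#' @rdname run_config
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname run_config
#' @export
read_config <- function(file) {
  if (!file.exists(file)) abort(paste0("file not found: ", file))
  cfg <- yaml::read_yaml(file)
  if (!is.list(cfg)) abort(paste0("malformed config in ", file))
  structure(cfg, class = "run_config")
}

#' Write the result tables of a run
#'
#' Writes one CSV per result table (ranked configurations, refinement
#' statistics, path-window diagnostics, affinities) with the configuration
#' hash embedded as a comment header; tables carrying different hashes are
#' refused.
#'
#' @param tables named list of tibbles; each may carry a `config_hash`
#'   attribute.
#' @param dir output directory (created if missing).
#' @param config the `run_config` of the run.
#' @return invisibly, the written file paths.
#' @export
write_report <- function(tables, dir, config) {
  hash <- config_hash(config)
  hashes <- purrr::compact(purrr::map(tables, attr, "config_hash"))
  if (length(hashes) && !all(unlist(hashes) == hash)) {
    abort("refusing to mix artifacts from different config hashes")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(tables, function(tb, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(paste0("# mcdock config_hash=", hash), con)
    close(con)
    suppressWarnings(write.table(as.data.frame(tb), path, sep = ",",
                                 row.names = FALSE, append = TRUE,
                                 qmethod = "double"))
    path
  })
  invisible(paths)
}

#' Read a report table, checking its hash
#'
#' @param file CSV written by [write_report()].
#' @return tibble with attribute `config_hash`.
#' @export
read_report_table <- function(file) {
  first <- readLines(file, n = 1)
  hash <- sub("^# mcdock config_hash=", "", first)
  out <- as_tibble(read.csv(file, comment.char = "#"))
  attr(out, "config_hash") <- hash
  out
}
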