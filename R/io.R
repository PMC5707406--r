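## Multi-model PDB and coupling-table I/O.  No pre-installed R PDB parser
## exists in this stack, so a minimal fixed-column reader/writer for
## ATOM/HETATM/MODEL/ENDMDL records is implemented here; that is the entire
## surface the ensemble format needs.

#' Read a conformer ensemble from a multi-model PDB file
#'
#' `MODEL`/`ENDMDL` blocks become frames; a file without `MODEL` records is
#' a single frame.  `ATOM` and `HETATM` records are both accepted (CDN
#' ligands in complexes are HETATM).  Atom count and ordering must be
#' identical across frames.
#'
#' @param path path to a PDB file.
#' @param residue_name optional: keep only records with this residue name
#'   (e.g. the ligand code of a CDN in a receptor complex).
#' @param cyclic passed to [conformer_ensemble()].
#' @return A [conformer_ensemble()].
#' @export
read_ensemble <- function(path, residue_name = NULL, cyclic = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  frames <- list()
  atoms_tab <- NULL
  cur_xyz <- NULL
  cur_atoms <- NULL
  in_model <- FALSE
  n_models <- 0L
  flush <- function() {
    if (is.null(cur_xyz) || length(cur_xyz) == 0) return()
    m <- do.call(rbind, cur_xyz)
    a <- do.call(rbind, cur_atoms)
    if (is.null(atoms_tab)) {
      atoms_tab <<- a
    } else if (nrow(a) != nrow(atoms_tab) ||
               !all(a$atom_name == atoms_tab$atom_name &
                    a$res_id == atoms_tab$res_id)) {
      stop(sprintf(
        "frame %d does not match frame 1 atom ordering (%d vs %d atoms)",
        length(frames) + 1L, nrow(a), nrow(atoms_tab)), call. = FALSE)
    }
    frames[[length(frames) + 1L]] <<- m
    cur_xyz <<- NULL
    cur_atoms <<- NULL
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      flush()
      in_model <- TRUE
      n_models <- n_models + 1L
    } else if (r == "ENDMDL") {
      flush()
      in_model <- FALSE
    } else if (r == "ATOM  " || r == "HETATM") {
      ln <- lines[i]
      name <- trimws(substr(ln, 13, 16))
      resn <- trimws(substr(ln, 18, 20))
      if (!is.null(residue_name) && resn != residue_name) next
      resi <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (anyNA(c(resi, x, y, z))) {
        stop(sprintf("unparseable %s record at line %d of %s",
                     trimws(r), i, path), call. = FALSE)
      }
      cur_xyz[[length(cur_xyz) + 1L]] <- c(x, y, z)
      cur_atoms[[length(cur_atoms) + 1L]] <- data.frame(
        res_id = resi, res_name = resn, atom_name = name,
        stringsAsFactors = FALSE)
    }
  }
  flush()
  if (length(frames) == 0) stop("no coordinates found in ", path,
                                call. = FALSE)
  frames <- lapply(frames, function(m) {
    colnames(m) <- NULL
    m
  })
  conformer_ensemble(frames, atoms_tab, cyclic = cyclic)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' @param e a [conformer_ensemble()].
#' @param path output path.
#' @param hetatm write `HETATM` instead of `ATOM` records.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(e, path, hetatm = FALSE) {
  stopifnot(inherits(e, "conformer_ensemble"))
  rectype <- if (hetatm) "HETATM" else "ATOM  "
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(e$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- e$frames[[f]]
    for (i in seq_len(nrow(m))) {
      nm <- e$atoms$atom_name[i]
      nm4 <- if (nchar(nm) <= 3) sprintf(" %-3s", nm) else
        sprintf("%-4s", nm)
      writeLines(sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f",
                         rectype, i, nm4,
                         substr(e$atoms$res_name[i], 1, 3), "A",
                         e$atoms$res_id[i], m[i, 1], m[i, 2], m[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read coupling tables (CSV or JSON) into coupling sets
#'
#' The CSV schema has columns `residue`, `fragment`, `J_Hz`, optional
#' `sigma_Hz`, `temperature_K` (extra columns are ignored); the JSON
#' equivalent is an array of objects with the same keys.  Rows are grouped
#' by `(residue, temperature_K)` into one [jcoupling_set()] each.
#'
#' @param path path to a `.csv` or `.json` file.
#' @param registry Karplus registry for fragment-vocabulary checking.
#' @return Named list of [jcoupling_set()] objects
#'   (`"<residue>@<temperature>K"`).
#' @export
read_couplings <- function(path, registry = load_karplus_registry()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  couplings_from_table(df, registry)
}

## shared grouping/validation for in-memory tables
couplings_from_table <- function(df, registry = load_karplus_registry()) {
  need <- c("residue", "fragment", "J_Hz", "temperature_K")
  if (!all(need %in% names(df))) {
    stop("coupling table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$sigma_Hz)) df$sigma_Hz <- NA_real_
  vocab <- coupling_vocabulary(registry)
  bad <- which(!(df$fragment %in% vocab))
  if (length(bad) > 0) {
    stop("unknown fragment label '", df$fragment[bad[1]], "' in row ",
         bad[1], call. = FALSE)
  }
  key <- paste(df$residue, df$fragment, df$temperature_K)
  if (anyDuplicated(key)) {
    stop("duplicate (residue, fragment, temperature) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  groups <- split(df, paste0(df$residue, "@", df$temperature_K, "K"))
  lapply(groups, function(g) {
    suppressWarnings(jcoupling_set(g$fragment, g$J_Hz, g$sigma_Hz,
                                   residue = g$residue[1],
                                   temperature_K = g$temperature_K[1],
                                   registry = registry))
  })
}
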