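# Readers and writers for the formats the pipeline consumes: PDB (single- and
# multi-model), FASTA, delimited feature tables and JSON configuration.
# Structures are held as plain data frames of atoms grouped by chain and
# residue; residue numbering is kept verbatim from the source file because
# residues are referred to by author numbering downstream (e.g. "S10", LIR1
# at 186-189).

STANDARD_AA <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by the readers and the synthetic-data
#' generators. Atoms are stored in file order; a residue is identified by the
#' key `(chain_id, residue_index, insertion_code)`.
#'
#' @param atoms data.frame with columns `chain_id`, `residue_index`,
#'   `insertion_code`, `residue_name`, `atom_name`, `element`, `x`, `y`, `z`,
#'   `is_heavy`.
#' @param model_id integer model identifier.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  required <- c("chain_id", "residue_index", "insertion_code", "residue_name",
                "atom_name", "element", "x", "y", "z", "is_heavy")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L) {
    stop("atom table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("a structure model must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  atoms$residue_key <- residue_key(atoms$chain_id, atoms$residue_index,
                                   atoms$insertion_code)
  structure(list(model_id = as.integer(model_id), atoms = atoms),
            class = "structure_model")
}

residue_key <- function(chain_id, residue_index, insertion_code = "") {
  ins <- ifelse(is.na(insertion_code) | insertion_code == "", "",
                insertion_code)
  paste0(chain_id, ":", residue_index, ins)
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain_id)
  cat("structure_model (model_id ", x$model_id, "): ",
      nrow(x$atoms), " atoms, ", length(ch), " chain(s) [",
      paste(names(ch), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' List chain identifiers of a structure model
#' @param model a `structure_model`.
#' @return Character vector of chain ids in file order.
#' @export
model_chains <- function(model) unique(model$atoms$chain_id)

# Atoms of one chain, in file order. Errors on unknown chains so that every
# downstream contact routine reports bad chain ids uniformly.
chain_atoms <- function(model, chain_id) {
  sel <- model$atoms$chain_id == chain_id
  if (!any(sel)) {
    stop("chain '", chain_id, "' not present in model (chains: ",
         paste(model_chains(model), collapse = ", "), ")")
  }
  model$atoms[sel, , drop = FALSE]
}

## ---------------------------------------------------------------------------
## PDB parsing (fixed columns, PDB 3.3). ATOM/HETATM/MODEL/ENDMDL only.

parse_float <- function(field, lineno, what) {
  v <- suppressWarnings(as.numeric(trimws(field)))
  bad <- is.na(v) & trimws(field) != ""
  bad <- bad | trimws(field) == ""
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("unparseable ", what, " field '", trimws(field[i]),
         "' on line ", lineno[i])
  }
  v
}

# Derive the element symbol: columns 77-78 when present, otherwise the first
# alphabetic character of the atom name after stripping digits (adequate for
# protein ATOM records, where names like "CA", "1HB" denote C and H).
derive_element <- function(elem_col, atom_name) {
  e <- toupper(trimws(elem_col))
  fallback <- toupper(sub("^[0-9]*", "", trimws(atom_name)))
  fallback <- substr(fallback, 1L, 1L)
  ifelse(e != "", e, fallback)
}

parse_pdb_lines <- function(lines, include_hetatm = FALSE) {
  rec <- substr(lines, 1L, 6L)
  is_atom <- startsWith(rec, "ATOM")
  is_het <- startsWith(rec, "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")

  # model index per line: 0 before any MODEL record, then the running count
  model_no <- cumsum(is_model)
  keep <- is_atom | (include_hetatm & is_het)
  if (include_hetatm) {
    resn <- trimws(substr(lines, 18L, 20L))
    keep <- keep & !(is_het & resn %in% c("HOH", "WAT", "DOD"))
  }
  if (!any(keep)) stop("no ATOM records found")
  ln <- which(keep)
  l <- lines[ln]

  atoms <- data.frame(
    lineno = ln,
    model_no = model_no[ln],
    atom_name = trimws(substr(l, 13L, 16L)),
    altloc = substr(l, 17L, 17L),
    residue_name = trimws(substr(l, 18L, 20L)),
    chain_id = trimws(substr(l, 22L, 22L)),
    residue_index = suppressWarnings(as.integer(trimws(substr(l, 23L, 26L)))),
    insertion_code = trimws(substr(l, 27L, 27L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$residue_index)) {
    i <- which(is.na(atoms$residue_index))[1L]
    stop("unparseable residue number on line ", ln[i])
  }
  atoms$x <- parse_float(substr(l, 31L, 38L), ln, "x coordinate")
  atoms$y <- parse_float(substr(l, 39L, 46L), ln, "y coordinate")
  atoms$z <- parse_float(substr(l, 47L, 54L), ln, "z coordinate")
  occ <- suppressWarnings(as.numeric(trimws(substr(l, 55L, 60L))))
  atoms$occupancy <- ifelse(is.na(occ), 1, occ)
  atoms$element <- derive_element(substr(l, 77L, 78L), atoms$atom_name)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))

  # altloc policy: keep highest occupancy per (model, chain, residue, atom
  # name); tie broken by first encountered.
  alt <- atoms$altloc != " " & atoms$altloc != ""
  if (any(alt)) {
    key <- paste(atoms$model_no, atoms$chain_id, atoms$residue_index,
                 atoms$insertion_code, atoms$atom_name, sep = "\r")
    ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$model_no, atoms$chain_id,
                                     atoms$residue_index,
                                     atoms$insertion_code, atoms$atom_name,
                                     sep = "\r")), , drop = FALSE]
    atoms <- atoms[order(atoms$lineno), , drop = FALSE]
  }
  split(atoms, atoms$model_no)
}

#' Read a PDB structure
#'
#' Parses ATOM (and optionally HETATM) records from a PDB file using fixed
#' columns. Hydrogens are retained but flagged `is_heavy = FALSE`; waters and
#' other HETATM groups are skipped unless `include_hetatm = TRUE`; for
#' alternate locations the highest-occupancy copy is kept (ties: first
#' encountered). Residue numbering and insertion codes are preserved verbatim.
#'
#' @param path path to a PDB file.
#' @param strict if `TRUE`, a multi-model file is an error; otherwise the
#'   first model is returned with a warning.
#' @param include_hetatm include non-water HETATM records.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, strict = FALSE, include_hetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !nzchar(paste(lines, collapse = ""))) {
    stop("empty file: ", path)
  }
  models <- parse_pdb_lines(lines, include_hetatm = include_hetatm)
  if (length(models) > 1L) {
    if (strict) stop("file contains ", length(models),
                     " models; use read_ensemble()")
    warning("file contains ", length(models), " models; returning the first")
  }
  structure_model(models[[1L]], model_id = 1L)
}

#' Write a structure model as PDB
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  writeLines(format_pdb_model(model$atoms), path)
  invisible(path)
}

format_pdb_model <- function(atoms) {
  # atom names of 1-3 characters start in column 14 by convention
  nm <- ifelse(nchar(atoms$atom_name) < 4L,
               sprintf(" %-3s", atoms$atom_name),
               sprintf("%-4s", atoms$atom_name))
  sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(atoms)) %% 100000L, nm, atoms$residue_name,
          atoms$chain_id, atoms$residue_index,
          ifelse(atoms$insertion_code == "", " ", atoms$insertion_code),
          atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
}

#' Read a model ensemble
#'
#' Accepts either a multi-model PDB file (MODEL/ENDMDL blocks; a file without
#' MODEL records yields an ensemble of one) or a directory of single-model
#' PDB files taken in lexicographic order. Input order is preserved as the
#' model rank and `model_id` is assigned 1..n in that order.
#'
#' @param path file or directory.
#' @param strict error (rather than warn) on inconsistent atom counts across
#'   models.
#' @return An object of class `ensemble`: a list with `models` (list of
#'   `structure_model`).
#' @export
read_ensemble <- function(path, strict = FALSE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0L) stop("no PDB files found in directory: ", path)
    models <- lapply(files, function(f) parse_pdb_lines(readLines(f, warn = FALSE))[[1L]])
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    models <- parse_pdb_lines(readLines(path, warn = FALSE))
  }
  if (length(models) == 0L) stop("no models found in ", path)
  counts <- vapply(models, nrow, integer(1))
  if (length(unique(counts)) > 1L) {
    msg <- paste0("inconsistent atom counts across models: ",
                  paste(counts, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  new_ensemble(lapply(seq_along(models), function(i) {
    structure_model(models[[i]], model_id = i)
  }))
}

new_ensemble <- function(models) {
  if (length(models) == 0L) stop("an ensemble must contain at least one model")
  ids <- vapply(models, function(m) m$model_id, integer(1))
  if (anyDuplicated(ids)) stop("model_ids must be unique")
  structure(list(models = models), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble of", length(x$models), "model(s)\n")
  invisible(x)
}

#' Read a trajectory
#'
#' A trajectory is a fixed topology plus an ordered list of coordinate
#' frames. Frames are read from a multi-model PDB or from a standard XYZ file
#' (blocks of "n / comment / n atom lines"); each frame must match the
#' topology's atom count.
#'
#' @param topology_path PDB file defining atoms, chains and residues.
#' @param frames_path multi-model PDB or XYZ file with the frame coordinates.
#' @param frame_times optional numeric frame labels.
#' @return An object of class `trajectory` with fields `topology`, `frames`
#'   (list of n_atoms x 3 matrices) and `frame_times`.
#' @export
read_trajectory <- function(topology_path, frames_path, frame_times = NULL) {
  topology <- read_structure(topology_path)
  lines <- readLines(frames_path, warn = FALSE)
  if (any(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))) {
    models <- parse_pdb_lines(lines)
    frames <- lapply(models, function(a) as.matrix(a[, c("x", "y", "z")]))
  } else {
    frames <- parse_xyz_blocks(lines)
  }
  new_trajectory(topology, frames, frame_times)
}

parse_xyz_blocks <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("expected an atom count on line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    coords <- t(vapply(strsplit(trimws(block), "\\s+"), function(tok) {
      as.numeric(tok[(length(tok) - 2L):length(tok)])
    }, numeric(3)))
    frames[[length(frames) + 1L]] <- coords
    i <- i + 2L + n
  }
  frames
}

new_trajectory <- function(topology, frames, frame_times = NULL) {
  if (length(frames) < 1L) stop("a trajectory needs at least one frame")
  n <- nrow(topology$atoms)
  counts <- vapply(frames, nrow, integer(1))
  bad <- which(counts != n)
  if (length(bad) > 0L) {
    stop("frame ", bad[1L], " has ", counts[bad[1L]],
         " atoms but the topology has ", n)
  }
  frames <- lapply(frames, function(f) {
    f <- unname(as.matrix(f))
    storage.mode(f) <- "double"
    f
  })
  structure(list(topology = topology, frames = frames,
                 frame_times = frame_times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frame(s) over",
      nrow(x$topology$atoms), "atoms\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## FASTA

#' Read amino-acid sequences from a FASTA file
#'
#' Sequences are uppercased and whitespace is stripped; the alphabet is
#' restricted to the 20 standard residues plus X. A sequence line before any
#' header, or an illegal character, is an error.
#'
#' @param path FASTA file.
#' @return A list of `sequence_record` objects (fields `id`, `sequence`).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) stop("sequence line before any FASTA header")
  idx <- cumsum(is_header)
  records <- lapply(split(seq_along(lines), idx), function(ii) {
    id <- trimws(sub("^>\\s*", "", lines[ii[1L]]))
    id <- strsplit(id, "\\s+")[[1L]][1L]
    seq <- toupper(gsub("\\s", "", paste(lines[ii[-1L]], collapse = "")))
    sequence_record(id, seq)
  })
  unname(records)
}

#' Construct a sequence record
#' @param id record identifier.
#' @param sequence amino-acid string (uppercased; standard 20 letters plus X).
#' @return A `sequence_record`.
#' @export
sequence_record <- function(id, sequence) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) < 1L) stop("empty sequence for record '", id, "'")
  letters_ <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(letters_), c(STANDARD_AA, "X"))
  if (length(bad) > 0L) {
    stop("illegal character '", bad[1L], "' in sequence '", id, "'")
  }
  structure(list(id = id, sequence = sequence), class = "sequence_record")
}

## ---------------------------------------------------------------------------
## Delimited tables

TABLE_SCHEMAS <- list(
  cells = c("cell_id", "well_id", "replicate", "condition", "genotype"),
  facs = c("cell_line", "condition", "replicate", "mfi_mcherry", "mfi_gfp"),
  samples = c("sample_id", "condition", "replicate"),
  lfq = c("protein_id")
)

#' Read a delimited table against a named schema
#'
#' Delimiter is inferred from the header line (tab if present, else comma).
#' Empty strings and "NaN" parse as missing, never as zero.
#'
#' @param path TSV/CSV file with a header row.
#' @param schema one of `"cells"`, `"facs"`, `"samples"`, `"lfq"` — the set
#'   of required columns to validate against.
#' @return data.frame.
#' @export
read_table_schema <- function(path, schema = c("cells", "facs", "samples", "lfq")) {
  schema <- match.arg(schema)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw_names <- strsplit(header, sep, fixed = TRUE)[[1L]]
  dup <- raw_names[duplicated(raw_names)]
  if (length(dup) > 0L) {
    stop("duplicate column name(s): ", paste(unique(dup), collapse = ", "))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA", "NaN"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- TABLE_SCHEMAS[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read an LFQ intensity matrix with its sample sheet
#'
#' @param matrix_path table with a `protein_id` column and one numeric column
#'   per sample (linear-scale intensities; blanks/NaN are missing).
#' @param samples_path sample sheet with columns `sample_id`, `condition`,
#'   `replicate`.
#' @return An `lfq_matrix`: list with `intensities` (proteins x samples),
#'   `samples` (annotation data.frame).
#' @export
read_lfq <- function(matrix_path, samples_path) {
  mat_df <- read_table_schema(matrix_path, "lfq")
  samples <- read_table_schema(samples_path, "samples")
  sample_cols <- setdiff(names(mat_df), "protein_id")
  missing <- setdiff(samples$sample_id, sample_cols)
  if (length(missing) > 0L) {
    stop("sample(s) in sheet absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  m <- as.matrix(mat_df[, samples$sample_id, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- mat_df$protein_id
  lfq_matrix(m, samples)
}

#' Construct an LFQ matrix object
#'
#' @param intensities numeric matrix, proteins x samples, linear scale;
#'   missing values as `NA`.
#' @param samples data.frame with `sample_id`, `condition`, `replicate`;
#'   `sample_id` must match `colnames(intensities)`.
#' @return An `lfq_matrix`.
#' @export
lfq_matrix <- function(intensities, samples) {
  stopifnot(is.matrix(intensities))
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- paste0("P", seq_len(nrow(intensities)))
  }
  if (!identical(colnames(intensities), as.character(samples$sample_id))) {
    stop("matrix column names must equal samples$sample_id, in order")
  }
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (anyNA(samples$condition)) stop("every sample needs a condition label")
  structure(list(intensities = intensities, samples = samples),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat("lfq_matrix:", nrow(x$intensities), "proteins x",
      ncol(x$intensities), "samples; conditions:",
      paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Read a JSON configuration file
#' @param path JSON file.
#' @return Parsed list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write machine-readable results as JSON
#' @param x list to serialize.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
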