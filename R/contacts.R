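# Soft residue-residue contact statistic between two chains.
#
# The per-atom-pair weight is the smooth switching function
#   sigma(r) = 0.5 - 0.5 * tanh((r - a) / b)
# which is ~1 well below the cutoff a, exactly 0.5 at r = a, and decays to 0
# above it with smoothing width b. Residue-pair weights sum sigma over all
# selected atom pairs, and the chain-pair total AB_cnts is the grand sum.
# Defaults: a = 5 Angstrom, b = 0.5 for atomistic structures (heavy atoms);
# a = 10, b = 1.0 for coarse-grained ones (one designated bead per residue).
#
# No periodic-boundary minimum-image handling: inputs are assumed to be whole
# molecules, already unwrapped upstream.

#' Contact-counting parameters
#'
#' @param mode `"atomistic"` (defaults a = 5, b = 0.5, heavy atoms) or
#'   `"coarse_grained"` (defaults a = 10, b = 1.0, one designated bead per
#'   residue).
#' @param a cutoff distance in Angstrom; the weight is exactly 0.5 at `r = a`.
#' @param b smoothing width in Angstrom.
#' @param atom_rule `"heavy_atoms"` or `"named_bead"`.
#' @param bead_name bead used when `atom_rule = "named_bead"`.
#' @return A `contact_params` object.
#' @export
contact_params <- function(mode = c("atomistic", "coarse_grained"),
                           a = NULL, b = NULL, atom_rule = NULL,
                           bead_name = "BB") {
  mode <- match.arg(mode)
  if (is.null(a)) a <- if (mode == "atomistic") 5 else 10
  if (is.null(b)) b <- if (mode == "atomistic") 0.5 else 1.0
  if (is.null(atom_rule)) {
    atom_rule <- if (mode == "atomistic") "heavy_atoms" else "named_bead"
  }
  atom_rule <- match.arg(atom_rule, c("heavy_atoms", "named_bead"))
  if (!is.numeric(a) || length(a) != 1L || a <= 0) stop("a must be > 0")
  if (!is.numeric(b) || length(b) != 1L || b <= 0) stop("b must be > 0")
  structure(list(mode = mode, a = a, b = b, atom_rule = atom_rule,
                 bead_name = bead_name),
            class = "contact_params")
}

#' Smooth sigmoidal contact weight
#'
#' `sigma(r) = 0.5 - 0.5 * tanh((r - a) / b)`: a smooth counting function
#' limiting contributions to atom pairs below the cutoff. Strictly decreasing
#' in `r`, equal to 0.5 at the cutoff, approaching 1 as `r -> 0` (for
#' `a >> b`) and 0 far above the cutoff.
#'
#' @param r distance(s) in Angstrom, `>= 0`.
#' @param params a `contact_params` object.
#' @return Weight(s) in (0, 1).
#' @export
contact_weight <- function(r, params = contact_params()) {
  if (any(r < 0)) stop("distances must be non-negative")
  0.5 - 0.5 * tanh((r - params$a) / params$b)
}

# Atom selection per the parameter set's atom rule.
select_atoms <- function(model, chain_id, params) {
  at <- chain_atoms(model, chain_id)
  at <- switch(params$atom_rule,
    heavy_atoms = at[at$is_heavy, , drop = FALSE],
    named_bead = at[at$atom_name == params$bead_name, , drop = FALSE]
  )
  if (nrow(at) == 0L) {
    stop("chain '", chain_id, "' has no atoms selected under rule '",
         params$atom_rule, "'")
  }
  at
}

# All pairwise Euclidean distances between two coordinate sets (rows).
cross_distances <- function(xa, xb) {
  sq <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(pmax(sq, 0))
}

# Shared workhorse: per-residue-pair aggregation of a per-atom-pair quantity.
# `combine` is "sum" (contact weights) or "min" (distances).
residue_pair_aggregate <- function(model, chain_a, chain_b, params, combine,
                                   value_fun) {
  at_a <- select_atoms(model, chain_a, params)
  at_b <- select_atoms(model, chain_b, params)
  xa <- as.matrix(at_a[, c("x", "y", "z")])
  xb <- as.matrix(at_b[, c("x", "y", "z")])
  v <- value_fun(cross_distances(xa, xb))

  keys_a <- unique(at_a$residue_key)
  keys_b <- unique(at_b$residue_key)
  fa <- factor(at_a$residue_key, levels = keys_a)
  fb <- factor(at_b$residue_key, levels = keys_b)
  # collapse atom rows to residues, then atom columns to residues
  agg <- if (combine == "sum") {
    t(rowsum(t(rowsum(v, fa)), fb))
  } else {
    ra <- apply(v, 2L, function(col) tapply(col, fa, min))
    ra <- matrix(ra, nrow = length(keys_a),
                 dimnames = list(keys_a, NULL))
    t(apply(ra, 1L, function(row) tapply(row, fb, min)))
    }
  agg <- matrix(as.numeric(agg), nrow = length(keys_a),
                dimnames = list(keys_a, keys_b))
  agg
}

#' Residue-level contact map between two chains
#'
#' Weight `w[p, q]` is the sum of the sigmoidal weight over all selected atom
#' pairs `(i in residue p of chain_a, j in residue q of chain_b)`; the grand
#' total is the chain-pair contact count AB_cnts.
#'
#' @param model a `structure_model`.
#' @param chain_a,chain_b chain identifiers.
#' @param params a `contact_params`.
#' @return A `contact_map`: list with `chain_a`, `chain_b`, `residues_a`,
#'   `residues_b`, `weights` (matrix) and `ab_total`.
#' @export
residue_contact_map <- function(model, chain_a, chain_b,
                                params = contact_params()) {
  w <- residue_pair_aggregate(model, chain_a, chain_b, params, "sum",
                              function(d) contact_weight(d, params))
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 residues_a = rownames(w), residues_b = colnames(w),
                 weights = w, ab_total = sum(w), params = params),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map ", x$chain_a, " x ", x$chain_b, ": ",
      length(x$residues_a), " x ", length(x$residues_b),
      " residues, AB_cnts = ", format(x$ab_total, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Chain-pair contact total (AB_cnts)
#'
#' @param map a `contact_map`.
#' @return The grand sum of the residue-pair weight matrix.
#' @export
chain_contact_total <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  sum(map$weights)
}

#' Binarized view of a contact map
#'
#' For plotting: a residue pair is "in contact" when its summed soft weight
#' reaches `threshold`. The soft map is the primary representation.
#'
#' @param map a `contact_map`.
#' @param threshold weight at or above which a pair counts as a contact.
#' @return Logical matrix with the map's residue axes.
#' @export
binarize_contact_map <- function(map, threshold = 0.5) {
  map$weights >= threshold
}

#' Minimum heavy-atom distance map between two chains
#'
#' @param model a `structure_model`.
#' @param chain_a,chain_b chain identifiers.
#' @param params a `contact_params` (controls atom selection only).
#' @return A `distance_map` with `d[p, q]` = minimum selected-atom Euclidean
#'   distance (Angstrom) between residues p and q.
#' @export
min_distance_map <- function(model, chain_a, chain_b,
                             params = contact_params()) {
  d <- residue_pair_aggregate(model, chain_a, chain_b, params, "min", identity)
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 residues_a = rownames(d), residues_b = colnames(d),
                 d = d),
            class = "distance_map")
}

#' Per-frame contact totals over a trajectory
#'
#' Applies the chain-pair contact statistic independently to every frame of
#' a trajectory, in frame order.
#'
#' @param traj a `trajectory`.
#' @param chain_a,chain_b chain identifiers in the topology.
#' @param params a `contact_params`.
#' @param keep_maps keep the full per-frame residue-pair weight matrices.
#' @return A `contact_series`: list with `frame` (index), `time` (label or
#'   index), `ab_total` (numeric vector) and optionally `maps`.
#' @export
contact_timeseries <- function(traj, chain_a, chain_b,
                               params = contact_params(),
                               keep_maps = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  topo <- traj$topology
  maps <- lapply(traj$frames, function(fr) {
    m <- topo
    m$atoms$x <- fr[, 1L]
    m$atoms$y <- fr[, 2L]
    m$atoms$z <- fr[, 3L]
    residue_contact_map(m, chain_a, chain_b, params)
  })
  times <- if (is.null(traj$frame_times)) seq_along(maps) else traj$frame_times
  structure(list(frame = seq_along(maps), time = times,
                 ab_total = vapply(maps, `[[`, numeric(1), "ab_total"),
                 maps = if (keep_maps) maps else NULL),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat("contact_series over", length(x$ab_total), "frames; AB_cnts range [",
      format(min(x$ab_total), digits = 4), ",",
      format(max(x$ab_total), digits = 4), "]\n")
  invisible(x)
}

#' Write a contact or distance map as TSV
#'
#' Residue keys of chain A become the first column, those of chain B the
#' remaining column headers.
#'
#' @param map a `contact_map` or `distance_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  m <- if (inherits(map, "contact_map")) map$weights else map$d
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
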