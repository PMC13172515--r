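# Seeded synthetic-data generators with recorded ground truth, one per
# pipeline stage. Each generator is a pure function of its configuration and
# seed and returns the dataset together with a truth record sufficient to
# script every recovery test downstream.
#
# Toy structures use one heavy atom per residue (a CA pseudo-atom), which
# keeps the oracle contact computation trivial and isolates the sigmoidal
# counting math from geometry bookkeeping.

truth_record <- function(generator, seed, params, labels = NULL) {
  structure(list(generator = generator, seed = seed, params = params,
                 labels = labels),
            class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat("truth_record [", x$generator, "], seed ", x$seed, "\n", sep = "")
  utils::str(x$params, max.level = 1)
  invisible(x)
}

ca_atoms <- function(chain_id, residue_index, coords) {
  data.frame(chain_id = chain_id,
             residue_index = as.integer(residue_index),
             insertion_code = "",
             residue_name = "GLY", atom_name = "CA", element = "C",
             x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
             is_heavy = TRUE, stringsAsFactors = FALSE)
}

#' Generate a two-chain toy complex with planted contacts
#'
#' Single-heavy-atom residues: chain A lies on a line with 30 Angstrom
#' spacing; chain B residues are parked 200 Angstrom away except the planted
#' ones, each placed at exactly its requested distance from its chain-A
#' partner. All non-planted inter-chain distances exceed 30 Angstrom
#' (> 3x either default cutoff).
#'
#' @param n_res_a,n_res_b residue counts of chains A and B.
#' @param planted_pairs list of `c(res_a, res_b, distance)` triples
#'   (residue indices 1-based, distance in Angstrom > 0). A chain-B residue
#'   may be planted at most once.
#' @param seed integer seed (recorded; placement is deterministic).
#' @return list `model` (a `structure_model`), `truth` (a `truth_record`).
#' @export
gen_two_chain_complex <- function(n_res_a, n_res_b, planted_pairs,
                                  seed = 1L) {
  spacing <- 30
  xa <- cbind((seq_len(n_res_a) - 1L) * spacing, 0, 0)
  xb <- cbind((seq_len(n_res_b) - 1L) * spacing, 200, 0)
  if (length(planted_pairs) > 0L) {
    pb <- vapply(planted_pairs, `[`, numeric(1), 2L)
    if (anyDuplicated(pb)) {
      stop("infeasible placement: a chain-B residue is planted twice")
    }
    for (k in seq_along(planted_pairs)) {
      pp <- planted_pairs[[k]]
      ia <- pp[1L]; ib <- pp[2L]; d <- pp[3L]
      if (d <= 0) stop("planted distances must be > 0")
      if (ia > n_res_a || ib > n_res_b) {
        stop("planted pair (", ia, ", ", ib, ") outside chain sizes")
      }
      # distinct directions in the (+y, z) half-plane keep simultaneously
      # planted residues apart and every distance increasing under +y pulls
      theta <- (k - 1L) * pi / (2L * length(planted_pairs))
      xb[ib, ] <- xa[ia, ] + d * c(0, cos(theta), sin(theta))
    }
  }
  atoms <- rbind(ca_atoms("A", seq_len(n_res_a), xa),
                 ca_atoms("B", seq_len(n_res_b), xb))
  list(model = structure_model(atoms),
       truth = truth_record("two_chain_complex", seed,
                            list(n_res_a = n_res_a, n_res_b = n_res_b,
                                 planted_pairs = planted_pairs)))
}

# Largest-remainder apportionment of n into named fractions; ties broken by
# earlier position. Documented so fraction-recovery tests are exact.
largest_remainder <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0L) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  stats::setNames(as.integer(base), names(fractions))
}

# Docked core positions: four residues spanning the two pocket clusters.
MODE_GEOMETRY <- list(
  hp1 = rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0)),
  hp2 = rbind(c(10, 0, 0), c(12, 0, 0), c(10, 2, 0), c(12, 2, 0)),
  docked = rbind(c(1, 1, 2.5), c(4.33, 1, 2.5), c(7.67, 1, 2.5),
                 c(11, 1, 2.5))
)

#' Generate an ensemble with planted LDS binding modes
#'
#' Builds a toy ATG8-like chain whose two hydrophobic pockets are clusters of
#' four atoms each, plus one candidate chain per mode label. In each model
#' exactly the planted mode's candidate sits in the docked pose spanning both
#' pockets; all other candidates are parked > 150 Angstrom away. Per-mode
#' model counts follow largest-remainder rounding of `n_models * fraction`;
#' modes are assigned to models in blocks, in the order of `mode_fractions`.
#'
#' The first mode label of the form "LIRk-..." is realized as a LIR-motif
#' candidate (4 core residues numbered 186-189 on its own chain); other
#' modes are whole-chain candidates.
#'
#' @param n_models ensemble size.
#' @param mode_fractions named numeric vector summing to 1; names are mode
#'   labels (e.g. `c("LIR1-LDS" = 0.72, "ATG7-LDS" = 0.28)`).
#' @param seed integer seed (recorded; geometry is deterministic).
#' @return list `ensemble`, `lds` (an `lds_definition`), `candidates`,
#'   `truth` (planted label per model).
#' @export
gen_mode_ensemble <- function(n_models, mode_fractions, seed = 1L) {
  if (n_models < 1L) stop("n_models must be >= 1")
  counts <- largest_remainder(n_models, mode_fractions)
  modes <- names(mode_fractions)
  stems <- sub("-LDS$", "", modes)

  lds <- lds_definition("TOY-ATG8", "B", hp1_residues = 1:4,
                        hp2_residues = 5:8)
  candidates <- lapply(seq_along(modes), function(i) {
    if (grepl("^LIR[0-9]+$", stems[i])) {
      lds_candidate(stems[i], chain_id = LETTERS[2L + i],
                    start = 186L, end = 189L)
    } else {
      lds_candidate(stems[i], chain_id = LETTERS[2L + i])
    }
  })
  planted <- rep(modes, counts)

  g <- MODE_GEOMETRY
  models <- lapply(seq_len(n_models), function(m) {
    atoms <- rbind(ca_atoms("B", 1:4, g$hp1), ca_atoms("B", 5:8, g$hp2))
    for (i in seq_along(candidates)) {
      cand <- candidates[[i]]
      resid <- if (is.null(cand$start)) 1:4 else cand$start:cand$end
      pos <- if (modes[i] == planted[m]) {
        g$docked
      } else {
        sweep(g$docked, 2L, c(0, 200 + 100 * i, 0), "+")
      }
      atoms <- rbind(atoms, ca_atoms(cand$chain_id, resid, pos))
    }
    structure_model(atoms, model_id = m)
  })
  list(ensemble = new_ensemble(models), lds = lds, candidates = candidates,
       truth = truth_record("mode_ensemble", seed,
                            list(n_models = n_models,
                                 mode_fractions = mode_fractions,
                                 counts = counts),
                            labels = planted))
}

#' Generate a trajectory in which the interface dissolves
#'
#' Chain B is rigidly translated along +y by `k * displacement_per_frame` in
#' frame k (k = 0 for the first frame, which equals the base complex). For
#' complexes built by [gen_two_chain_complex()] every inter-chain distance is
#' strictly increasing along the trajectory, so any soft contact series over
#' it is strictly decreasing.
#'
#' @param base_complex a `structure_model` with chains A and B (e.g. from
#'   [gen_two_chain_complex()]).
#' @param n_frames number of frames, `>= 1`.
#' @param displacement_per_frame Angstrom per frame, `> 0`.
#' @param chain_id chain to translate.
#' @param seed integer seed (recorded; construction is deterministic).
#' @return list `trajectory`, `truth`.
#' @export
gen_decay_trajectory <- function(base_complex, n_frames,
                                 displacement_per_frame, chain_id = "B",
                                 seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (displacement_per_frame <= 0) stop("displacement must be > 0")
  base <- as.matrix(base_complex$atoms[, c("x", "y", "z")])
  moving <- base_complex$atoms$chain_id == chain_id
  if (!any(moving)) stop("chain '", chain_id, "' not in base complex")
  frames <- lapply(seq_len(n_frames) - 1L, function(k) {
    fr <- base
    fr[moving, 2L] <- fr[moving, 2L] + k * displacement_per_frame
    fr
  })
  list(trajectory = new_trajectory(base_complex, frames,
                                   frame_times = seq_len(n_frames) - 1L),
       truth = truth_record("decay_trajectory", seed,
                            list(n_frames = n_frames,
                                 displacement_per_frame =
                                   displacement_per_frame,
                                 chain_id = chain_id)))
}

#' Generate a spiked LFQ matrix
#'
#' Baseline log2 abundances are drawn per protein from
#' `Normal(baseline_mean, baseline_sd^2)`; spiked proteins are shifted by
#' `log2_effect` in the bait group; replicate noise is
#' `Normal(0, within_sd^2)`; entries are removed completely at random at
#' `missing_rate`; the emitted matrix is linear scale.
#'
#' @param n_proteins,n_spiked protein counts (`n_spiked <= n_proteins`).
#' @param log2_effect bait-group shift of spiked proteins (log2 units).
#' @param within_sd replicate noise sd (log2 units).
#' @param missing_rate completely-at-random missingness in `[0, 1)`.
#' @param n_per_group replicates per condition, `>= 2`.
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd baseline log2 abundance distribution.
#' @param bait_condition,control_condition condition labels.
#' @return list `lfq` (an `lfq_matrix`, linear scale), `truth` (spiked ids).
#' @export
gen_lfq <- function(n_proteins, n_spiked = 0L, log2_effect = 3,
                    within_sd = 0.3, missing_rate = 0, n_per_group = 3L,
                    seed = 1L, baseline_mean = 25, baseline_sd = 2,
                    bait_condition = "bait", control_condition = "control") {
  if (n_spiked > n_proteins) stop("n_spiked must be <= n_proteins")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  with_seed(seed, {
    ids <- sprintf("P%05d", seq_len(n_proteins))
    spiked <- if (n_spiked > 0L) sort(sample.int(n_proteins, n_spiked)) else integer(0)
    base <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    n_s <- 2L * n_per_group
    m <- matrix(base, n_proteins, n_s) +
      matrix(stats::rnorm(n_proteins * n_s, 0, within_sd), n_proteins, n_s)
    m[spiked, seq_len(n_per_group)] <- m[spiked, seq_len(n_per_group)] +
      log2_effect
    if (missing_rate > 0) {
      m[stats::runif(length(m)) < missing_rate] <- NA_real_
    }
    lin <- 2^m
    rownames(lin) <- ids
    samples <- data.frame(
      sample_id = c(paste0(bait_condition, "_", seq_len(n_per_group)),
                    paste0(control_condition, "_", seq_len(n_per_group))),
      condition = rep(c(bait_condition, control_condition),
                      each = n_per_group),
      replicate = rep(seq_len(n_per_group), 2L),
      stringsAsFactors = FALSE
    )
    colnames(lin) <- samples$sample_id
    list(lfq = lfq_matrix(lin, samples),
         truth = truth_record("lfq", seed,
                              list(n_proteins = n_proteins,
                                   log2_effect = log2_effect,
                                   within_sd = within_sd,
                                   missing_rate = missing_rate,
                                   n_per_group = n_per_group),
                              labels = ids[spiked]))
  })
}

#' Generate a single-cell feature table with planted group effects
#'
#' Each design entry defines one condition/genotype group: its cell count,
#' replicate label and per-feature mean/sd. Features are drawn from normals
#' clamped at 0; cells are assigned round-robin to `wells_per_group` wells
#' within the group.
#'
#' @param design list of groups, each a list with `condition`, `genotype`,
#'   `n_cells`, optional `replicate` (default 1) and `features` (named list
#'   of `c(mean, sd)` pairs).
#' @param wells_per_group wells per group for round-robin assignment.
#' @param seed integer seed.
#' @return list `cells` (data.frame), `truth`.
#' @export
gen_cell_table <- function(design, wells_per_group = 2L, seed = 1L) {
  if (length(design) == 0L) stop("design is empty")
  with_seed(seed, {
    blocks <- lapply(seq_along(design), function(gi) {
      g <- design[[gi]]
      n <- g$n_cells
      if (is.null(n) || n < 1L) stop("each group needs n_cells >= 1")
      rep_lab <- if (is.null(g$replicate)) 1L else g$replicate
      df <- data.frame(
        cell_id = sprintf("g%d_c%04d", gi, seq_len(n)),
        well_id = sprintf("%s_%s_r%s_w%d", g$condition, g$genotype, rep_lab,
                          ((seq_len(n) - 1L) %% wells_per_group) + 1L),
        replicate = rep_lab,
        condition = g$condition,
        genotype = g$genotype,
        stringsAsFactors = FALSE
      )
      for (f in names(g$features)) {
        ms <- g$features[[f]]
        df[[f]] <- pmax(0, stats::rnorm(n, ms[[1L]], ms[[2L]]))
      }
      df
    })
    all_feats <- unique(unlist(lapply(blocks, names)))
    blocks <- lapply(blocks, function(b) {
      for (f in setdiff(all_feats, names(b))) b[[f]] <- NA_real_
      b[, all_feats, drop = FALSE]
    })
    cells <- do.call(rbind, blocks)
    rownames(cells) <- NULL
    list(cells = cells,
         truth = truth_record("cell_table", seed,
                              list(design = design,
                                   wells_per_group = wells_per_group)))
  })
}

#' Generate a FACS MFI table with planted reporter-ratio effects
#'
#' Per sample, the GFP MFI is drawn around `gfp_mfi` with lognormal noise and
#' the mCherry MFI is set so the reporter ratio equals
#' `base_ratio * effect * (1 + noise)`. Effects default to 1; the untreated
#' condition must be present for every cell line.
#'
#' @param lines cell-line labels.
#' @param conditions condition labels; must include `untreated_label`.
#' @param base_ratio untreated mCherry/GFP ratio.
#' @param effects named list: `effects[[line]][[condition]]` multiplicative
#'   ratio effect (missing entries default to 1).
#' @param noise_sd relative sd of the ratio noise.
#' @param n_replicates samples per line x condition.
#' @param seed integer seed.
#' @param untreated_label untreated condition label.
#' @param gfp_mfi typical GFP MFI.
#' @return list `facs` (data.frame), `truth`.
#' @export
gen_facs_table <- function(lines, conditions, base_ratio = 2,
                           effects = list(), noise_sd = 0.05,
                           n_replicates = 3L, seed = 1L,
                           untreated_label = "UT", gfp_mfi = 1e4) {
  if (!untreated_label %in% conditions) {
    stop("conditions must include the untreated label '", untreated_label, "'")
  }
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        condition = conditions, cell_line = lines,
                        stringsAsFactors = FALSE)
    eff <- mapply(function(l, cnd) {
      e <- effects[[l]][[cnd]]
      if (is.null(e)) 1 else e
    }, grid$cell_line, grid$condition)
    gfp <- gfp_mfi * exp(stats::rnorm(nrow(grid), 0, 0.1))
    ratio <- base_ratio * eff * (1 + stats::rnorm(nrow(grid), 0, noise_sd))
    facs <- data.frame(cell_line = grid$cell_line,
                       condition = grid$condition,
                       replicate = grid$replicate,
                       mfi_mcherry = gfp * ratio,
                       mfi_gfp = gfp,
                       stringsAsFactors = FALSE)
    list(facs = facs,
         truth = truth_record("facs", seed,
                              list(base_ratio = base_ratio,
                                   effects = effects,
                                   noise_sd = noise_sd,
                                   n_replicates = n_replicates),
                              labels = eff))
  })
}
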