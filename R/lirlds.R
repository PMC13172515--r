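# LIR motif scanning and geometric classification of which binding partner
# occupies the LIR-docking site (LDS) of an ATG8 protein.
#
# The LIR core is the 4-residue consensus [W/F/Y]-x-x-[L/I/V]; the LDS is the
# ATG8 surface formed by two hydrophobic pockets (HP1, receives the aromatic
# core position 1; HP2, receives the hydrophobic position 4). A candidate
# (a LIR motif of some chain, or a whole chain) is called the occupant of the
# LDS when its soft-contact weight into both pockets clears configurable
# thresholds; per-model calls aggregate to ensemble occupancy percentages.

LIR_P1 <- c("W", "F", "Y")
LIR_P4 <- c("L", "I", "V")

#' Scan a sequence for LIR core motifs
#'
#' Reports every 4-residue window matching the consensus
#' `[W/F/Y]-x-x-[L/I/V]`, overlapping windows included, in ascending start
#' order (1-based inclusive coordinates).
#'
#' @param seq a `sequence_record`, or a plain amino-acid string.
#' @param id record id used when `seq` is a plain string.
#' @return data.frame with columns `record_id`, `start`, `end`, `core`,
#'   `label` (LIR1, LIR2, ... in order of occurrence).
#' @export
scan_lir <- function(seq, id = "seq") {
  if (inherits(seq, "sequence_record")) {
    id <- seq$id
    s <- seq$sequence
  } else {
    s <- sequence_record(id, seq)$sequence
  }
  n <- nchar(s)
  aa <- strsplit(s, "")[[1L]]
  hits <- integer(0)
  if (n >= 4L) {
    starts <- seq_len(n - 3L)
    hits <- starts[aa[starts] %in% LIR_P1 & aa[starts + 3L] %in% LIR_P4]
  }
  data.frame(
    record_id = rep(id, length(hits)),
    start = hits,
    end = hits + 3L,
    core = vapply(hits, function(i) substr(s, i, i + 3L), character(1)),
    label = if (length(hits)) paste0("LIR", seq_along(hits)) else character(0),
    stringsAsFactors = FALSE
  )
}

#' Define an ATG8 LIR-docking site
#'
#' @param atg8_id name of the ATG8 protein (e.g. "GABARAPL2").
#' @param chain_id chain carrying the ATG8 in the model.
#' @param hp1_residues,hp2_residues residue indices (source numbering) lining
#'   hydrophobic pockets 1 and 2; non-empty and disjoint.
#' @return An `lds_definition`.
#' @export
lds_definition <- function(atg8_id, chain_id, hp1_residues, hp2_residues) {
  if (length(hp1_residues) == 0L || length(hp2_residues) == 0L) {
    stop("pocket residue lists must be non-empty")
  }
  if (length(intersect(hp1_residues, hp2_residues)) > 0L) {
    stop("HP1 and HP2 residue lists must be disjoint")
  }
  structure(list(atg8_id = atg8_id, chain_id = chain_id,
                 hp1_residues = as.integer(hp1_residues),
                 hp2_residues = as.integer(hp2_residues)),
            class = "lds_definition")
}

#' Shipped LDS pocket definitions
#'
#' Curated default pocket residue sets for GABARAPL2 and LC3B, drawn from
#' conserved annotations of the two hydrophobic pockets in the ATG8 family.
#' These are configuration defaults, intended as starting points; for other
#' ATG8s or non-standard numbering supply [lds_definition()] directly.
#'
#' @param atg8_id `"GABARAPL2"` or `"LC3B"`.
#' @param chain_id chain carrying the ATG8.
#' @return An `lds_definition`.
#' @export
lds_defaults <- function(atg8_id = c("GABARAPL2", "LC3B"), chain_id = "B") {
  atg8_id <- match.arg(atg8_id)
  if (atg8_id == "GABARAPL2") {
    lds_definition("GABARAPL2", chain_id,
                   hp1_residues = c(17, 21, 50, 51, 104),
                   hp2_residues = c(49, 52, 55, 60, 63))
  } else {
    lds_definition("LC3B", chain_id,
                   hp1_residues = c(19, 23, 53, 54, 108),
                   hp2_residues = c(52, 55, 63, 66, 70))
  }
}

#' Define an LDS occupancy candidate
#'
#' A candidate is either a LIR motif (the atoms of its 4 core residues plus a
#' configurable flank) or a whole chain (e.g. a co-factor protein).
#'
#' @param label mode label stem (e.g. "LIR1", "ATG7").
#' @param chain_id chain carrying the candidate.
#' @param start,end 1-based residue span of the motif core; both `NULL` for a
#'   whole-chain candidate.
#' @param flank residues added on each side of a motif span.
#' @return An `lds_candidate`.
#' @export
lds_candidate <- function(label, chain_id, start = NULL, end = NULL,
                          flank = 2L) {
  if (xor(is.null(start), is.null(end))) {
    stop("give both start and end, or neither")
  }
  structure(list(label = label, chain_id = chain_id,
                 start = start, end = end, flank = as.integer(flank)),
            class = "lds_candidate")
}

candidate_atoms <- function(model, cand, params) {
  at <- select_atoms(model, cand$chain_id, params)
  if (!is.null(cand$start)) {
    lo <- cand$start - cand$flank
    hi <- cand$end + cand$flank
    at <- at[at$residue_index >= lo & at$residue_index <= hi, , drop = FALSE]
    if (nrow(at) == 0L) {
      stop("candidate '", cand$label, "': no atoms in residue span ",
           lo, "-", hi, " of chain ", cand$chain_id)
    }
  }
  at
}

pocket_atoms <- function(model, lds, residues, pocket, params) {
  at <- select_atoms(model, lds$chain_id, params)
  at <- at[at$residue_index %in% residues, , drop = FALSE]
  found <- unique(at$residue_index)
  missing <- setdiff(residues, found)
  if (length(missing) > 0L) {
    stop(pocket, " residue(s) absent from chain ", lds$chain_id, ": ",
         paste(missing, collapse = ", "))
  }
  at
}

#' Soft-contact weight of each candidate into the two LDS pockets
#'
#' For every candidate, sums the sigmoidal contact weight over all selected
#' atom pairs between the candidate's atoms and the atoms of the HP1 and HP2
#' pocket residues.
#'
#' @param model a `structure_model`.
#' @param lds an `lds_definition`.
#' @param candidates list of `lds_candidate` objects.
#' @param params a `contact_params`.
#' @return data.frame with columns `label`, `chain_id`, `hp1`, `hp2`, `total`.
#' @export
pocket_contact_weights <- function(model, lds, candidates,
                                   params = contact_params()) {
  if (length(candidates) == 0L) stop("candidate list is empty")
  hp1 <- pocket_atoms(model, lds, lds$hp1_residues, "HP1", params)
  hp2 <- pocket_atoms(model, lds, lds$hp2_residues, "HP2", params)
  x1 <- as.matrix(hp1[, c("x", "y", "z")])
  x2 <- as.matrix(hp2[, c("x", "y", "z")])
  rows <- lapply(candidates, function(cand) {
    xc <- as.matrix(candidate_atoms(model, cand, params)[, c("x", "y", "z")])
    w1 <- sum(contact_weight(cross_distances(xc, x1), params))
    w2 <- sum(contact_weight(cross_distances(xc, x2), params))
    data.frame(label = cand$label, chain_id = cand$chain_id,
               hp1 = w1, hp2 = w2, total = w1 + w2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classification thresholds for LDS occupancy calls
#'
#' @param min_weight minimum total (HP1 + HP2) soft-contact weight for a
#'   candidate to count as engaging the LDS at all.
#' @param min_pocket_weight minimum weight required in each pocket
#'   individually for a clean occupancy call.
#' @param margin relative margin: if the top two candidate totals differ by
#'   less than this fraction of the top total, the call is flagged ambiguous.
#' @return A `classification_rules` object.
#' @export
classification_rules <- function(min_weight = 1.0, min_pocket_weight = 0.25,
                                 margin = 0.10) {
  structure(list(min_weight = min_weight,
                 min_pocket_weight = min_pocket_weight,
                 margin = margin),
            class = "classification_rules")
}

candidate_start <- function(cand) if (is.null(cand$start)) Inf else cand$start

#' Classify which candidate occupies the LDS in one model
#'
#' The occupant is the candidate with the largest total pocket weight,
#' provided its total reaches `rules$min_weight` and both pockets
#' individually reach `rules$min_pocket_weight`. If no candidate reaches
#' `min_weight` the model is "unoccupied". If the top two totals (among
#' candidates reaching `min_weight`) differ by less than `rules$margin`
#' relative to the top, or the top candidate engages only one pocket, the
#' call is "ambiguous" — the provisional occupant is then the tied candidate
#' with the lowest motif start (whole chains rank after motifs) and the
#' ambiguity flag is set.
#'
#' @param model a `structure_model`.
#' @param lds an `lds_definition`.
#' @param candidates list of `lds_candidate` objects (non-empty).
#' @param rules a `classification_rules`.
#' @param params a `contact_params`.
#' @return A `binding_mode_call`: list with `model_id`, `mode_label`,
#'   `occupant`, `pocket_weights`, `margin`, `ambiguous`.
#' @export
classify_binding_mode <- function(model, lds, candidates,
                                  rules = classification_rules(),
                                  params = contact_params()) {
  w <- pocket_contact_weights(model, lds, candidates, params)
  starts <- vapply(candidates, candidate_start, numeric(1))
  engaged <- w$total >= rules$min_weight

  call <- list(model_id = model$model_id, pocket_weights = w,
               rules = rules, ambiguous = FALSE, margin = NA_real_)
  if (!any(engaged)) {
    call$mode_label <- "unoccupied"
    call$occupant <- NULL
    return(structure(call, class = "binding_mode_call"))
  }

  we <- w[engaged, , drop = FALSE]
  se <- starts[engaged]
  # rank by total, descending; ties by lowest motif start, then input order
  ord <- order(-we$total, se, seq_len(nrow(we)))
  top <- ord[1L]
  top_total <- we$total[top]
  runner <- if (nrow(we) >= 2L) we$total[ord[2L]] else 0
  call$margin <- top_total - runner

  both_pockets <- we$hp1[top] >= rules$min_pocket_weight &&
    we$hp2[top] >= rules$min_pocket_weight
  close_race <- nrow(we) >= 2L &&
    (top_total - runner) < rules$margin * top_total

  call$occupant <- list(label = we$label[top], chain_id = we$chain_id[top])
  if (close_race || !both_pockets) {
    call$ambiguous <- TRUE
    call$mode_label <- "ambiguous"
  } else {
    call$mode_label <- paste0(we$label[top], "-LDS")
  }
  structure(call, class = "binding_mode_call")
}

#' @export
print.binding_mode_call <- function(x, ...) {
  cat("binding_mode_call [model ", x$model_id, "]: ", x$mode_label,
      if (x$ambiguous) " (ambiguous)" else "",
      "; margin = ", format(x$margin, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Binding-mode occupancy over an ensemble
#'
#' Classifies every model independently and tabulates counts and percentages
#' per mode label (including "unoccupied" and "ambiguous" when they occur).
#'
#' @param ensemble an `ensemble`.
#' @param lds an `lds_definition`.
#' @param candidates list of `lds_candidate` objects.
#' @param rules a `classification_rules`.
#' @param params a `contact_params`.
#' @return An `occupancy_summary`: list with `n_models`, `table` (data.frame
#'   `mode_label`, `count`, `percent`), `calls` and the thresholds used.
#' @export
ensemble_occupancy <- function(ensemble, lds, candidates,
                               rules = classification_rules(),
                               params = contact_params()) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (length(ensemble$models) == 0L) stop("ensemble is empty")
  calls <- lapply(ensemble$models, classify_binding_mode,
                  lds = lds, candidates = candidates,
                  rules = rules, params = params)
  labels <- vapply(calls, `[[`, character(1), "mode_label")
  tab <- table(factor(labels, levels = unique(labels)))
  summary_df <- data.frame(mode_label = names(tab),
                           count = as.integer(tab),
                           percent = 100 * as.integer(tab) / length(calls),
                           stringsAsFactors = FALSE)
  structure(list(n_models = length(calls), table = summary_df,
                 calls = calls, rules = rules),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat("occupancy_summary over", x$n_models, "models:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Percentage of models assigned a given mode
#'
#' @param summary an `occupancy_summary`.
#' @param mode_label mode of interest (e.g. "LIR1-LDS").
#' @return Percentage (0 if the mode never occurs).
#' @export
occupancy_percent <- function(summary, mode_label) {
  i <- match(mode_label, summary$table$mode_label)
  if (is.na(i)) 0 else summary$table$percent[i]
}
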