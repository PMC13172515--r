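# Fixture builders shared across test files. All fixtures are constructed in
# code at test time.

# A minimal PDB ATOM line with standard fixed columns.
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, element = NULL, record = "ATOM  ",
                     altloc = " ", icode = " ") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%s%5d %s%s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno, icode,
          x, y, z, occ, 0, element)
}

write_toy_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

# Three-atom two-chain toy: two CA in chain A, one CA in chain B.
toy_pdb_3atoms <- function() {
  write_toy_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(3, "CA", "LEU", "B", 1, 0, 5, 0),
    "END"
  ))
}

# Random toy complex for oracle-equivalence tests: two chains, <= max_atoms
# atoms total, residues with 1-3 heavy atoms plus occasional hydrogens,
# coordinates in a box small enough that many pairs are within the cutoff.
random_toy_complex <- function(max_atoms = 50, box = 12) {
  repeat {
    n_res_a <- sample(1:5, 1)
    n_res_b <- sample(1:5, 1)
    make_chain <- function(chain, n_res) {
      rows <- lapply(seq_len(n_res), function(r) {
        n_at <- sample(1:3, 1)
        data.frame(chain_id = chain, residue_index = r, insertion_code = "",
                   residue_name = "ALA",
                   atom_name = paste0("C", seq_len(n_at)),
                   element = sample(c("C", "N", "O", "H"), n_at,
                                    replace = TRUE, prob = c(3, 1, 1, 1)),
                   x = runif(n_at, 0, box), y = runif(n_at, 0, box),
                   z = runif(n_at, 0, box),
                   is_heavy = NA, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    atoms <- rbind(make_chain("A", n_res_a), make_chain("B", n_res_b))
    atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
    heavy_ok <- all(tapply(atoms$is_heavy, atoms$chain_id, any))
    if (nrow(atoms) <= max_atoms && heavy_ok) {
      return(structure_model(atoms))
    }
  }
}

# Brute-force contact/distance oracle: plain nested loops over all selected
# atom pairs, independent of the package's vectorized path.
oracle_maps <- function(model, chain_a, chain_b, a = 5, b = 0.5) {
  sel <- function(ch) {
    at <- model$atoms[model$atoms$chain_id == ch & model$atoms$is_heavy, ]
    split(at, factor(at$residue_key, levels = unique(at$residue_key)))
  }
  ra <- sel(chain_a); rb <- sel(chain_b)
  w <- matrix(0, length(ra), length(rb), dimnames = list(names(ra), names(rb)))
  d <- matrix(Inf, length(ra), length(rb),
              dimnames = list(names(ra), names(rb)))
  for (p in seq_along(ra)) {
    for (q in seq_along(rb)) {
      for (i in seq_len(nrow(ra[[p]]))) {
        for (j in seq_len(nrow(rb[[q]]))) {
          dx <- ra[[p]]$x[i] - rb[[q]]$x[j]
          dy <- ra[[p]]$y[i] - rb[[q]]$y[j]
          dz <- ra[[p]]$z[i] - rb[[q]]$z[j]
          r <- sqrt(dx^2 + dy^2 + dz^2)
          w[p, q] <- w[p, q] + 0.5 - 0.5 * tanh((r - a) / b)
          d[p, q] <- min(d[p, q], r)
        }
      }
    }
  }
  list(w = w, d = d)
}

# Brute-force Benjamini-Hochberg step-up: q_i = min over j >= rank(i) of
# p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  for (k in seq_len(m)) adj[k] <- min(adj[k:m])
  q[ord] <- pmin(adj, 1)
  q
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n1+n2, n1) group assignments (no ties assumed).
oracle_wilcox_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_null <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  min(1, mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-9))
}

# Rigid-body transform helper: random rotation (QR of a Gaussian matrix) +
# translation applied to all atoms of a model.
random_rigid_transform <- function(model) {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_ <- runif(3, -50, 50)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t_[1]
  model$atoms$y <- xyz[, 2] + t_[2]
  model$atoms$z <- xyz[, 3] + t_[3]
  model
}
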