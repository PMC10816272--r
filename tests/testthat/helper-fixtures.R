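# Shared fixtures and independent oracles.  The pocket is deterministic,
# so it is built once per test run.

.fixtures <- new.env()

fixturePocket <- function() {
  if (is.null(.fixtures$pocket)) .fixtures$pocket <- genPocket()
  .fixtures$pocket
}

fixtureReceptors <- function() {
  pk <- fixturePocket()
  out <- list(HDAC11 = pk$receptor)
  for (iso in c("HDAC1", "HDAC6", "HDAC8")) {
    r <- pk$receptor
    r@isoform <- iso
    out[[iso]] <- r
  }
  out
}

# random rigid transform (proper rotation + translation)
randomRigid <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr <- qr(A)
  R <- qr.Q(qr)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

applyRigid <- function(coords, rig) {
  sweep(coords %*% t(rig$R), 2, rig$t, "+")
}

# --- exhaustive pharmacophore oracle --------------------------------------
# Enumerates every injective assignment of hypothesis features to ligand
# features (no kind-based candidate pruning: incompatible kinds are
# rejected per assignment), aligns and checks each one, and returns the
# lowest accepted anchor RMSD.  Independent of the matcher's search.

.permutations <- function(v, k) {
  if (k == 0) return(list(integer()))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i], k - 1)) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

oracleMatch <- function(mol, hypothesis) {
  feats <- hypothesis@features
  centers <- as.matrix(feats[, c("x", "y", "z")])
  best <- NULL
  for (ci in seq_along(conformers(mol))) {
    lig <- perceiveFeatures(mol, ci)
    if (nrow(lig) < nrow(feats)) next
    anchors <- as.matrix(lig[, c("x", "y", "z")])
    heavy <- conformers(mol)[[ci]][mol@atoms$elem != "H", , drop = FALSE]
    for (perm in .permutations(seq_len(nrow(lig)), nrow(feats))) {
      if (!all(lig$kind[perm] == feats$kind)) next
      fit <- kabsch(centers, anchors[perm, , drop = FALSE])
      aligned <- applyTransform(anchors[perm, , drop = FALSE], fit)
      if (any(sqrt(rowSums((aligned - centers)^2)) > feats$tolerance)) next
      hv <- applyTransform(heavy, fit)
      clash <- FALSE
      for (v in seq_len(nrow(hypothesis@volumes))) {
        vc <- unlist(hypothesis@volumes[v, c("x", "y", "z")])
        if (any(sqrt(rowSums(sweep(hv, 2, vc)^2)) <
                hypothesis@volumes$radius[v])) {
          clash <- TRUE
          break
        }
      }
      if (clash) next
      if (is.null(best) || fit$rmsd < best) best <- fit$rmsd
    }
  }
  best
}

# --- rotation-grid superposition oracle -----------------------------------
# Exhaustive search over a zyz Euler grid (degrees).  Uses the trace
# formulation: rmsd^2 = (|P|^2 + |Q|^2 - 2 max tr(R M)) / n with
# M = P^T Q over centered coordinates.

gridSuperposeRMSD <- function(reference, mobile, stepDeg = 2) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)
  const <- sum(P^2) + sum(Q^2)
  n <- nrow(P)
  ab <- expand.grid(b = seq(0, 180, by = stepDeg) * pi / 180,
                    c = seq(0, 358, by = stepDeg) * pi / 180)
  cb <- cos(ab$b); sb <- sin(ab$b); cc <- cos(ab$c); sc <- sin(ab$c)
  bestT <- -Inf
  for (aDeg in seq(0, 358, by = stepDeg)) {
    a <- aDeg * pi / 180
    ca <- cos(a); sa <- sin(a)
    # R = Rz(a) Ry(b) Rz(c), expanded entrywise
    r11 <- ca * cb * cc - sa * sc
    r12 <- -ca * cb * sc - sa * cc
    r13 <- ca * sb
    r21 <- sa * cb * cc + ca * sc
    r22 <- -sa * cb * sc + ca * cc
    r23 <- sa * sb
    r31 <- -sb * cc
    r32 <- sb * sc
    r33 <- cb
    tr <- r11 * M[1, 1] + r12 * M[2, 1] + r13 * M[3, 1] +
      r21 * M[1, 2] + r22 * M[2, 2] + r23 * M[3, 2] +
      r31 * M[1, 3] + r32 * M[2, 3] + r33 * M[3, 3]
    mx <- max(tr)
    if (mx > bestT) bestT <- mx
  }
  sqrt(max(0, (const - 2 * bestT) / n))
}
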