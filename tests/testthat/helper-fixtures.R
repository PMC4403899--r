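## Shared fixtures, built in code and memoized for the session.

.fix <- new.env(parent = emptyenv())

toyStructures <- function() {
  if (is.null(.fix$structures))
    .fix$structures <- list(makeToyStructure(40, "helix", seed = 1),
                            makeToyStructure(60, "hairpin", seed = 2),
                            makeToyStructure(30, "cluster", seed = 3))
  .fix$structures
}

toySSF <- function() {
  if (is.null(.fix$ssf)) .fix$ssf <- compileSSFModels(toyStructures())
  .fix$ssf
}

## small grids keep the suite fast; the searched-grid behaviour itself is
## covered by dedicated tests
fastConfig <- function(hidden = 5L)
  agentConfig(hiddenGrid = hidden, gammaGrid = 1 / 9, costGrid = 1,
              maxit = 150L)

toyRecords <- function(n = 300L, noise = 0.5, seed = 3L)
  makeSyntheticRecords(n, demoBeta(), noise, seed = seed)

toyEnsemble <- function() {
  if (is.null(.fix$ensemble))
    .fix$ensemble <- trainAgents(toyRecords(350L), fastConfig(), seed = 1L)
  .fix$ensemble
}

## an ensemble whose seven agents each predict a fixed constant: routes and
## consensus arithmetic become fully controllable
constantEnsemble <- function(mlr, annG, annStab, annDestab,
                             svrG, svrStab, svrDestab, sigmaMax = 2) {
  const <- function(v, method, spec)
    new("AgentModel", method = "MLR", specialization = spec,
        fit = list(coef = c(v, rep(0, 9))), info = list())
  new("AgentEnsemble",
      agents = list(mlr = const(mlr, "MLR", "general"),
                    ann_general = const(annG, "ANN", "general"),
                    ann_stabilizing = const(annStab, "ANN", "stabilizing"),
                    ann_destabilizing = const(annDestab, "ANN", "destabilizing"),
                    svr_general = const(svrG, "SVR", "general"),
                    svr_stabilizing = const(svrStab, "SVR", "stabilizing"),
                    svr_destabilizing = const(svrDestab, "SVR", "destabilizing")),
      center = setNames(rep(0, 9), FEATURE_NAMES),
      scale = setNames(rep(1, 9), FEATURE_NAMES),
      sigmaMax = sigmaMax, config = list())
}

zeroFeatures <- function() setNames(rep(0, 9), FEATURE_NAMES)

## a bare residue table row; coordinates given as CA, CB defaults to CA + x
residueRow <- function(chain, resno, aa, ca, cb = ca + c(1.53, 0, 0),
                       n = ca + c(-1.46, 0, 0), cc = ca + c(0.5, 1.4, 0),
                       sg = c(NA_real_, NA_real_, NA_real_), icode = "",
                       cbVirtual = FALSE) {
  data.frame(chain = chain, resno = resno, icode = icode, aa = aa,
             n_x = n[1], n_y = n[2], n_z = n[3],
             ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
             c_x = cc[1], c_y = cc[2], c_z = cc[3],
             cb_x = cb[1], cb_y = cb[2], cb_z = cb[3],
             sg_x = sg[1], sg_y = sg[2], sg_z = sg[3],
             cb_virtual = cbVirtual, stringsAsFactors = FALSE)
}

structureFromRows <- function(..., sourceId = "manual") {
  new("ProteinStructure", residues = do.call(rbind, list(...)),
      sourceId = sourceId, model = 1L)
}

## rigid-body transform of a whole structure (for invariance tests)
rigidTransform <- function(st, angles = c(0.4, -0.9, 1.7),
                           trans = c(5, -3, 12)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  rot <- rz(angles[3]) %*% rx(angles[2]) %*% rz(angles[1])
  r <- st@residues
  for (p in c("n_", "ca_", "c_", "cb_", "sg_")) {
    cols <- paste0(p, c("x", "y", "z"))
    xyz <- as.matrix(r[, cols])
    ok <- stats::complete.cases(xyz)
    if (any(ok))
      r[ok, cols] <- sweep(xyz[ok, , drop = FALSE] %*% t(rot), 2, trans, "+")
  }
  st@residues <- r
  st
}

## fixed-width PDB ATOM line (for hand-crafted parser fixtures)
pdbAtomLine <- function(serial, name, resn, chain, resno, x, y, z,
                        occ = 1, alt = " ", icode = " ", type = "ATOM  ") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f  0.00",
          type, serial, name, alt, resn, chain, resno, icode, x, y, z, occ)
}
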