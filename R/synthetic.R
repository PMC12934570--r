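#' Synthetic data configuration
#'
#' Parameters of the seeded generator emulating the five input tables: a
#' proteome of target families with shared pocket geometry, a chemical space
#' of drug chemotypes with shared embedding direction and fingerprint
#' archetype, a planted family-by-chemotype compatibility matrix as binding
#' truth, and PPI records concentrated within families.
#'
#' Noise defaults are calibrated so that within-family pocket similarity
#' exceeds the 0.95 edge threshold and within-chemotype drug similarity
#' exceeds the 0.8 threshold, with cross-group similarities falling below;
#' [generateBundle()] verifies the realized margins and errors if they are
#' infeasible.
#'
#' @param nTargetFamilies,targetsPerFamily proteome structure.
#' @param pocketsPerTarget,residuesPerPocket,residueEmbedDim pocket geometry.
#' @param withinFamilyNoise Gaussian noise SD around the family archetype
#'   (unit-norm) for residue embeddings.
#' @param nChemotypes,drugsPerChemotype,drugEmbedDim chemical space.
#' @param chemotypeNoise Gaussian noise SD around the chemotype archetype.
#' @param drugProfileWeight weight of the binding-profile component mixed
#'   into each chemotype's archetype (fixed random pharmacophore direction
#'   per compatible family). Controls how much of the binding rule is
#'   readable from the drug features alone versus only through the graph.
#' @param profileVisibleFraction fraction of families whose pharmacophore is
#'   chemically visible in the drug embeddings; the remaining families'
#'   compatibility is cryptic and reachable only through the graph.
#' @param fingerprintSize,fingerprintBits fingerprint length and archetype
#'   cardinality.
#' @param flipRate per-bit dropout rate of archetype bits (an equal expected
#'   number of random bits is added).
#' @param compatibilityDensity Bernoulli density of the family-by-chemotype
#'   compatibility matrix (every family and chemotype is guaranteed at least
#'   one compatible partner so no family detaches from the graph).
#' @param auxDrugsPerChemotype drugs per chemotype that appear only in the
#'   auxiliary (message-passing) binding source and never receive labels,
#'   emulating a knowledge-base drug pool much larger than the labeled set.
#' @param fpDecoupleRate probability that an aux-only drug's fingerprint is
#'   drawn from a different chemotype's archetype than its embedding.
#'   Fingerprint space and embedding space are only partially correlated in
#'   real chemistry; this is the channel through which auxiliary drugs
#'   similar to held-out chemistry can legitimately pass the medoid rule.
#' @param nLabeledInteractions,positiveFraction labeled set size and target
#'   positive fraction.
#' @param labelNoise probability of flipping a labeled example's label.
#' @param auxFraction auxiliary positive-only records as a fraction of the
#'   labeled set size (drawn over the aux-only drugs, so the pair sets are
#'   disjoint from the labeled pairs).
#' @param ppiWithinFamilyProb probability that a within-family target pair
#'   gets a passing PPI record.
#' @param ppiBackgroundProb probability that a cross-family pair gets a
#'   failing background PPI record.
#' @param seed integer seed.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(nTargetFamilies = 4L, targetsPerFamily = 10L,
                      pocketsPerTarget = 2L, residuesPerPocket = 4L,
                      residueEmbedDim = 32L, withinFamilyNoise = 0.03,
                      nChemotypes = 5L, drugsPerChemotype = 8L,
                      auxDrugsPerChemotype = 4L, fpDecoupleRate = 0.5,
                      drugEmbedDim = 32L, chemotypeNoise = 0.05,
                      drugProfileWeight = 0.25, profileVisibleFraction = 0.5,
                      fingerprintSize = 512L, fingerprintBits = 48L,
                      flipRate = 0.08, compatibilityDensity = 0.4,
                      nLabeledInteractions = 400L, positiveFraction = 0.5,
                      labelNoise = 0.02, auxFraction = 0.6,
                      ppiWithinFamilyProb = 0.25, ppiBackgroundProb = 0.01,
                      seed = 1L) {
  cfg <- list(
    nTargetFamilies = .assertCount(nTargetFamilies, "nTargetFamilies"),
    targetsPerFamily = .assertCount(targetsPerFamily, "targetsPerFamily"),
    pocketsPerTarget = .assertCount(pocketsPerTarget, "pocketsPerTarget"),
    residuesPerPocket = .assertCount(residuesPerPocket, "residuesPerPocket"),
    residueEmbedDim = .assertCount(residueEmbedDim, "residueEmbedDim"),
    withinFamilyNoise = as.numeric(withinFamilyNoise),
    nChemotypes = .assertCount(nChemotypes, "nChemotypes"),
    drugsPerChemotype = .assertCount(drugsPerChemotype, "drugsPerChemotype"),
    auxDrugsPerChemotype = .assertCount(auxDrugsPerChemotype,
                                        "auxDrugsPerChemotype", min = 0L),
    fpDecoupleRate = .assertProb(fpDecoupleRate, "fpDecoupleRate"),
    drugEmbedDim = .assertCount(drugEmbedDim, "drugEmbedDim"),
    chemotypeNoise = as.numeric(chemotypeNoise),
    drugProfileWeight = as.numeric(drugProfileWeight),
    profileVisibleFraction = .assertProb(profileVisibleFraction,
                                         "profileVisibleFraction"),
    fingerprintSize = .assertCount(fingerprintSize, "fingerprintSize"),
    fingerprintBits = .assertCount(fingerprintBits, "fingerprintBits"),
    flipRate = .assertProb(flipRate, "flipRate"),
    compatibilityDensity = .assertProb(compatibilityDensity, "compatibilityDensity"),
    nLabeledInteractions = .assertCount(nLabeledInteractions, "nLabeledInteractions"),
    positiveFraction = .assertProb(positiveFraction, "positiveFraction"),
    labelNoise = .assertProb(labelNoise, "labelNoise"),
    auxFraction = .assertProb(auxFraction, "auxFraction"),
    ppiWithinFamilyProb = .assertProb(ppiWithinFamilyProb, "ppiWithinFamilyProb"),
    ppiBackgroundProb = .assertProb(ppiBackgroundProb, "ppiBackgroundProb"),
    seed = .assertCount(seed, "seed", min = 0L))
  if (cfg$withinFamilyNoise < 0 || cfg$chemotypeNoise < 0)
    stop("noise levels must be nonnegative")
  structure(cfg, class = "SimConfig")
}

#' Strong-signal preset
#'
#' The frozen configuration used for planted-signal recovery checks: low
#' noise, dense compatibility, 2,400 labeled interactions over 5 families of
#' 40 targets and 8 chemotypes of 25 drugs.
#'
#' @param seed integer seed.
#' @return a [simConfig()].
#' @export
strongRegime <- function(seed = 1L) {
  simConfig(nTargetFamilies = 5L, targetsPerFamily = 40L,
            pocketsPerTarget = 2L, residuesPerPocket = 6L,
            residueEmbedDim = 32L, withinFamilyNoise = 0.03,
            nChemotypes = 8L, drugsPerChemotype = 25L,
            auxDrugsPerChemotype = 25L, fpDecoupleRate = 0.5,
            drugEmbedDim = 128L, chemotypeNoise = 0.025,
            drugProfileWeight = 0.3, profileVisibleFraction = 0.5,
            compatibilityDensity = 0.5, nLabeledInteractions = 2400L,
            positiveFraction = 0.5, labelNoise = 0.02, auxFraction = 1.0,
            ppiWithinFamilyProb = 0.25, ppiBackgroundProb = 0.005,
            seed = seed)
}

.unitRows <- function(x) x / sqrt(rowSums(x^2))

## Random family x chemotype compatibility at the configured density, with
## fix-ups guaranteeing every family AND every chemotype at least one
## compatible and one incompatible partner. Rows need both classes for the
## stratified labeled sampling; columns need both classes because a chemotype
## compatible with everything (or nothing) has no genuine negatives (or
## positives), which makes any held-out evaluation of it degenerate.
.drawCompatibility <- function(cfg) {
  compat <- matrix(stats::runif(cfg$nTargetFamilies * cfg$nChemotypes) <
                     cfg$compatibilityDensity,
                   cfg$nTargetFamilies, cfg$nChemotypes)
  for (i in which(rowSums(compat) == 0))
    compat[i, sample.int(cfg$nChemotypes, 1L)] <- TRUE
  for (i in which(rowSums(compat) == cfg$nChemotypes))
    compat[i, sample.int(cfg$nChemotypes, 1L)] <- FALSE
  for (j in which(colSums(compat) == 0)) {
    ## pick a well-connected family, but never fill a row completely
    cand <- which(rowSums(compat) < cfg$nChemotypes - 1L)
    if (!length(cand)) cand <- which(rowSums(compat) < cfg$nChemotypes)
    i <- cand[which.max(rowSums(compat)[cand])]
    compat[i, j] <- TRUE
  }
  for (j in which(colSums(compat) == cfg$nTargetFamilies)) {
    ## clear a cell of the family least likely to lose its last partner
    cand <- which(rowSums(compat) >= 2L)
    compat[cand[which.max(rowSums(compat)[cand])], j] <- FALSE
  }
  compat
}

#' Generate a synthetic bundle of the five input tables
#'
#' Draws one unit-norm archetype per target family and per drug chemotype;
#' residue and drug embeddings are archetype plus Gaussian noise,
#' renormalized. Binding truth is a seeded family-by-chemotype compatibility
#' matrix; labeled interactions are sampled to the configured positive
#' fraction with label noise, and auxiliary positives are sampled disjointly
#' from the labeled pairs. PPI records are within-family pairs with passing
#' confidence scores (drawn in \[700, 1000\]) plus cross-family background
#' records with failing scores (in \[0, 699\]). The generator verifies the
#' planted similarity margins against the default edge thresholds and errors
#' if the noise makes them infeasible.
#'
#' @param cfg a [simConfig()].
#' @return list of class `SyntheticBundle` with elements `residues`, `drugs`,
#'   `ppi`, `bind`, `bindMP`, `fingerprints`, and `truth` (family and
#'   chemotype labels, compatibility matrix, realized similarity margins,
#'   config echo).
#' @export
generateBundle <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  nT <- cfg$nTargetFamilies * cfg$targetsPerFamily
  nLab <- cfg$nChemotypes * cfg$drugsPerChemotype
  nAuxD <- cfg$nChemotypes * cfg$auxDrugsPerChemotype
  nD <- nLab + nAuxD
  tIds <- sprintf("T%04d", seq_len(nT))
  labIds <- sprintf("D%04d", seq_len(nLab))
  auxIds <- if (nAuxD) sprintf("X%04d", seq_len(nAuxD)) else character(0)
  dIds <- c(labIds, auxIds)
  famOf <- stats::setNames(rep(seq_len(cfg$nTargetFamilies),
                               each = cfg$targetsPerFamily), tIds)
  chemOf <- stats::setNames(
    c(rep(seq_len(cfg$nChemotypes), each = cfg$drugsPerChemotype),
      rep(seq_len(cfg$nChemotypes), each = cfg$auxDrugsPerChemotype)[seq_len(nAuxD)]),
    dIds)

  ## residue embeddings: family archetype + noise, renormalized
  famArch <- .unitRows(matrix(stats::rnorm(cfg$nTargetFamilies * cfg$residueEmbedDim),
                              cfg$nTargetFamilies))
  rPerT <- cfg$pocketsPerTarget * cfg$residuesPerPocket
  nRes <- nT * rPerT
  resEmb <- famArch[rep(famOf, each = rPerT), , drop = FALSE] +
    cfg$withinFamilyNoise * matrix(stats::rnorm(nRes * cfg$residueEmbedDim), nRes)
  resEmb <- .unitRows(resEmb)
  residues <- data.frame(
    target_id = rep(tIds, each = rPerT),
    pocket_id = paste0("p", rep(rep(seq_len(cfg$pocketsPerTarget),
                                    each = cfg$residuesPerPocket), nT)),
    residue_id = paste0("r", rep(seq_len(rPerT), nT)),
    stringsAsFactors = FALSE)
  residues$embedding <- resEmb

  ## binding truth first: the drug embeddings carry a binding-profile
  ## component, so compatibility must be drawn before the chemical space
  compat <- .drawCompatibility(cfg)

  ## drug embeddings and fingerprints. A chemotype's effective archetype is
  ## its identity direction plus gamma times the sum of fixed random
  ## "pharmacophore" directions of its compatible families: chemical
  ## language-model embeddings encode binding-relevant structure, so a
  ## fraction of the binding rule is readable from the features themselves
  ## (and transfers to chemotypes never seen in training); the rest of the
  ## signal is reachable only through the graph.
  chemArch <- .unitRows(matrix(stats::rnorm(cfg$nChemotypes * cfg$drugEmbedDim),
                               cfg$nChemotypes))
  pharm <- .unitRows(matrix(stats::rnorm(cfg$nTargetFamilies * cfg$drugEmbedDim),
                            cfg$nTargetFamilies))
  ## only a subset of families has a chemically visible pharmacophore; the
  ## rest of the binding rule is cryptic and reachable only through the graph
  nVis <- round(cfg$profileVisibleFraction * cfg$nTargetFamilies)
  visible <- sort(sample.int(cfg$nTargetFamilies, nVis))
  vmask <- as.numeric(seq_len(cfg$nTargetFamilies) %in% visible)
  profile <- (t(compat * vmask) %*% pharm) * cfg$drugProfileWeight
  chemEff <- .unitRows(chemArch + profile)
  drugEmb <- chemEff[chemOf, , drop = FALSE] +
    cfg$chemotypeNoise * matrix(stats::rnorm(nD * cfg$drugEmbedDim), nD)
  drugEmb <- .unitRows(drugEmb)
  drugs <- data.frame(drug_id = dIds,
                      smiles = paste0("SYN[", dIds, "]"),
                      stringsAsFactors = FALSE)
  drugs$embedding <- drugEmb
  fpArch <- lapply(seq_len(cfg$nChemotypes), function(i)
    sort(sample.int(cfg$fingerprintSize, cfg$fingerprintBits) - 1L))
  nAdd <- max(1L, round(cfg$flipRate * cfg$fingerprintBits))
  ## labeled drugs carry their own chemotype's fingerprint archetype; aux-only
  ## drugs are decoupled with probability fpDecoupleRate (fingerprint space
  ## and embedding space agree only partially, as in real chemistry)
  fpChem <- chemOf
  if (nAuxD && cfg$nChemotypes > 1L) {
    dec <- auxIds[stats::runif(nAuxD) < cfg$fpDecoupleRate]
    fpChem[dec] <- vapply(fpChem[dec], function(cc)
      .sampleFrom(setdiff(seq_len(cfg$nChemotypes), cc), 1L), integer(1))
  }
  fpBits <- lapply(dIds, function(d) {
    arch <- fpArch[[fpChem[[d]]]]
    keep <- arch[stats::runif(length(arch)) >= cfg$flipRate]
    extra <- .sampleFrom(setdiff(seq_len(cfg$fingerprintSize) - 1L, arch), nAdd)
    sort(unique(c(keep, extra)))
  })
  fps <- fingerprintSet(stats::setNames(fpBits, dIds), cfg$fingerprintSize)

  ## feasibility of the planted similarity margins
  margins <- .checkMargins(residues, famOf, drugEmb, chemOf)

  ## labeled interactions over the labeled drug pool only, stratified by
  ## target family so every family has the same label base rate. Curated DTI
  ## benchmarks are balanced by design; an unstratified draw would let models
  ## score held-out chemistry from per-family label frequencies alone.
  allT <- rep(seq_len(nT), times = nLab)
  allD <- rep(seq_len(nLab), each = nT)
  isPos <- compat[cbind(unname(famOf)[allT], unname(chemOf)[allD])]
  nPerFam <- round(cfg$nLabeledInteractions / cfg$nTargetFamilies)
  nPosF <- round(nPerFam * cfg$positiveFraction)
  sel <- integer(0); lab <- integer(0)
  for (f in seq_len(cfg$nTargetFamilies)) {
    inFam <- unname(famOf)[allT] == f
    posPool <- which(inFam & isPos); negPool <- which(inFam & !isPos)
    if (nPosF > length(posPool) || (nPerFam - nPosF) > length(negPool))
      stop("family ", f, " lacks enough compatible/incompatible pairs for ",
           "the requested labeled set")
    sel <- c(sel, .sampleFrom(posPool, nPosF), .sampleFrom(negPool, nPerFam - nPosF))
    lab <- c(lab, rep(1L, nPosF), rep(0L, nPerFam - nPosF))
  }
  flip <- stats::runif(length(lab)) < cfg$labelNoise
  lab[flip] <- 1L - lab[flip]
  ord <- order(sel)
  bind <- data.frame(drug = labIds[allD[sel]][ord],
                     target = tIds[allT[sel]][ord],
                     label = lab[ord], source = "prediction_set",
                     stringsAsFactors = FALSE)

  ## auxiliary positives over the aux-only drug pool, stratified the same way
  ## (pair sets disjoint from the labeled pairs by construction)
  nAux <- round(cfg$auxFraction * cfg$nLabeledInteractions)
  if (nAux > 0L && nAuxD == 0L)
    stop("auxFraction > 0 requires auxDrugsPerChemotype > 0")
  bindMP <- data.frame(drug = character(0), target = character(0),
                       label = integer(0), source = character(0),
                       stringsAsFactors = FALSE)
  if (nAux > 0L) {
    auxT <- rep(seq_len(nT), times = nAuxD)
    auxD <- rep(seq_len(nAuxD), each = nT)
    auxPos <- compat[cbind(unname(famOf)[auxT], unname(chemOf[auxIds])[auxD])]
    if (nAux > sum(auxPos))
      stop("not enough compatible aux-only pairs for the auxiliary set")
    ## stratified across families, redistributing the shortfall of families
    ## whose compatible-pair pool is smaller than their share
    pools <- lapply(seq_len(cfg$nTargetFamilies), function(f)
      which(unname(famOf)[auxT] == f & auxPos))
    want <- rep(floor(nAux / cfg$nTargetFamilies), cfg$nTargetFamilies)
    want[seq_len(nAux - sum(want))] <- want[seq_len(nAux - sum(want))] + 1L
    auxSel <- integer(0)
    repeat {
      take <- pmin(want, lengths(pools))
      for (f in seq_along(pools)) {
        if (take[f] > 0L) {
          pick <- .sampleFrom(pools[[f]], take[f])
          auxSel <- c(auxSel, pick)
          pools[[f]] <- setdiff(pools[[f]], pick)
        }
      }
      short <- nAux - length(auxSel)
      if (short <= 0L) break
      open <- which(lengths(pools) > 0L)
      want <- integer(cfg$nTargetFamilies)
      want[open] <- ceiling(short / length(open))
    }
    auxSel <- sort(auxSel[seq_len(nAux)])
    bindMP <- data.frame(drug = auxIds[auxD[auxSel]],
                         target = tIds[auxT[auxSel]],
                         label = 1L, source = "message_passing_set",
                         stringsAsFactors = FALSE)
  }

  ## PPI records
  famPairs <- which(outer(unname(famOf), unname(famOf), `==`) &
                      upper.tri(matrix(0, nT, nT)), arr.ind = TRUE)
  keepIn <- stats::runif(nrow(famPairs)) < cfg$ppiWithinFamilyProb
  inP <- famPairs[keepIn, , drop = FALSE]
  crossPairs <- which(outer(unname(famOf), unname(famOf), `!=`) &
                        upper.tri(matrix(0, nT, nT)), arr.ind = TRUE)
  keepBg <- stats::runif(nrow(crossPairs)) < cfg$ppiBackgroundProb
  bgP <- crossPairs[keepBg, , drop = FALSE]
  rint <- function(n, lo, hi) sample(seq.int(lo, hi), n, replace = TRUE)
  mkPPI <- function(pairs, passing) {
    n <- nrow(pairs)
    if (!n) return(NULL)
    data.frame(
      target_a = tIds[pairs[, 1L]], target_b = tIds[pairs[, 2L]],
      neighborhood = rint(n, 0, 699), fusion = rint(n, 0, 699),
      cooccurrence = rint(n, 0, 699),
      experimental = if (passing) rint(n, 700, 1000) else rint(n, 0, 699),
      database = if (passing) rint(n, 0, 1000) else rint(n, 0, 699),
      textmining = rint(n, 0, 699),
      combined = if (passing) rint(n, 700, 1000) else rint(n, 0, 699),
      stringsAsFactors = FALSE)
  }
  ppi <- rbind(mkPPI(inP, TRUE), mkPPI(bgP, FALSE))
  if (is.null(ppi)) {
    ppi <- data.frame(target_a = character(0), target_b = character(0),
                      neighborhood = integer(0), fusion = integer(0),
                      cooccurrence = integer(0), experimental = integer(0),
                      database = integer(0), textmining = integer(0),
                      combined = integer(0), stringsAsFactors = FALSE)
  }

  structure(list(
    residues = residues, drugs = drugs, ppi = ppi,
    bind = bind, bindMP = bindMP, fingerprints = fps,
    truth = list(family = famOf, chemotype = chemOf, fpChemotype = fpChem,
                 labeledDrugs = labIds, auxOnlyDrugs = auxIds,
                 compatibility = compat,
                 margins = margins, config = unclass(cfg))
  ), class = "SyntheticBundle")
}

## Verify the planted separation: within-family pocket similarity must exceed
## the default 0.95 target threshold, cross-family must fall below; likewise
## drug cosine similarity around the 0.8 threshold. Errors report realized
## quantiles so an infeasible noise setting is diagnosable.
.checkMargins <- function(residues, famOf, drugEmb, chemOf) {
  ids <- names(famOf)
  S <- .targetSimMatrix(residues, ids)
  same <- outer(unname(famOf), unname(famOf), `==`)
  diag(same) <- NA
  within <- S[which(same)]
  cross <- S[which(!same)]
  sD <- .unitRows(drugEmb) %*% t(.unitRows(drugEmb))
  sameD <- outer(unname(chemOf), unname(chemOf), `==`)
  diag(sameD) <- NA
  withinD <- sD[which(sameD)]
  crossD <- sD[which(!sameD)]
  qtl <- function(x) if (length(x)) stats::quantile(x, c(0, .5, 1)) else c(NA, NA, NA)
  fail <- character(0)
  if (length(within) && min(within) <= 0.95)
    fail <- c(fail, paste0("within-family pocket similarity min ",
                           round(min(within), 4), " <= 0.95"))
  if (length(cross) && max(cross) >= 0.95)
    fail <- c(fail, paste0("cross-family pocket similarity max ",
                           round(max(cross), 4), " >= 0.95"))
  if (length(withinD) && min(withinD) <= 0.8)
    fail <- c(fail, paste0("within-chemotype drug similarity min ",
                           round(min(withinD), 4), " <= 0.8"))
  if (length(crossD) && max(crossD) >= 0.8)
    fail <- c(fail, paste0("cross-chemotype drug similarity max ",
                           round(max(crossD), 4), " >= 0.8"))
  if (length(fail)) {
    stop("infeasible similarity margins for the configured noise: ",
         paste(fail, collapse = "; "),
         "; realized within-family quantiles: ",
         paste(round(qtl(within), 4), collapse = "/"),
         "; cross-family: ", paste(round(qtl(cross), 4), collapse = "/"))
  }
  list(target_within_min = if (length(within)) min(within) else NA_real_,
       target_cross_max = if (length(cross)) max(cross) else NA_real_,
       drug_within_min = if (length(withinD)) min(withinD) else NA_real_,
       drug_cross_max = if (length(crossD)) max(crossD) else NA_real_)
}

#' @export
print.SyntheticBundle <- function(x, ...) {
  cat("SyntheticBundle:", length(unique(x$residues$target_id)), "targets,",
      nrow(x$drugs), "drugs,", nrow(x$bind), "labeled and", nrow(x$bindMP),
      "auxiliary interactions\n")
  invisible(x)
}
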