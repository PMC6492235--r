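#' Simulate a random ultrametric chronogram
#'
#' Topology by successive random coalescence of lineages; internal-node
#' ages are sorted uniforms on `(0, rootAge)` assigned in coalescence
#' order, with the final (root) coalescence pinned at `rootAge`. All tips
#' are contemporaneous at age 0.
#'
#' @param nTips number of tips (>= 2).
#' @param rootAge root age in Ga.
#' @param seed mandatory RNG seed; the output is a deterministic function
#'   of `(nTips, rootAge, seed)`.
#' @param tipLabels optional tip names (default `t1..tn`).
#' @return List with `tree` (a [TimeTree-class]) and `truth` (data.frame
#'   of node, age).
#' @export
simulateChronogram <- function(nTips, rootAge, seed, tipLabels = NULL) {
  stopifnot(nTips >= 2)
  set.seed(seed)
  if (is.null(tipLabels)) tipLabels <- paste0("t", seq_len(nTips))
  agesInt <- if (nTips > 2) sort(runif(nTips - 2L, 0, rootAge)) else numeric(0)
  agesInt <- c(agesInt, rootAge)
  nwk <- as.list(tipLabels)
  age <- rep(0, nTips)
  for (k in seq_len(nTips - 1L)) {
    pick <- sample.int(length(nwk), 2L)
    a <- agesInt[k]
    merged <- sprintf("(%s:%.12g,%s:%.12g)", nwk[[pick[1]]], a - age[pick[1]],
                      nwk[[pick[2]]], a - age[pick[2]])
    nwk <- c(nwk[-pick], merged)
    age <- c(age[-pick], a)
  }
  tree <- readTimeTree(paste0(nwk[[1]], ";"))
  list(tree = tree,
       truth = data.frame(node = seq_along(tree@ages), age = tree@ages))
}

#' Simulate node rates on a chronogram
#'
#' Autocorrelated log-normal kind: a log-rate random walk down the tree
#' with per-edge variance `sigma2 * dt`. Without a trend the walk carries
#' the half-variance mean correction of the inference model
#' (`E[r_child] = r_parent`). With a trend
#' `nu(t) = nu_inf + amplitude * exp(-(t_root - t)/tau)` (fast early, slow
#' late), the expected log-rate change over an edge equals the trend
#' difference, and the root rate is set to `nu(t_root)`. Uncorrelated
#' gamma kind: i.i.d. mean-`rootRate` gamma draws per non-root node.
#'
#' @param tree a [TimeTree-class] with ages.
#' @param clock a [ClockModel-class].
#' @param trend optional list `(nu_inf, amplitude, tau)` in
#'   substitutions/site/Ga and Ga.
#' @param seed mandatory RNG seed.
#' @return List with `tree` (rates set) and `truth` (data.frame of node,
#'   age, rate, and expected subs/site on the edge above each node).
#' @export
simulateRates <- function(tree, clock, trend = NULL, seed) {
  set.seed(seed)
  phy <- tree@phylo
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  ages <- tree@ages
  kids <- .childrenList(phy)
  rates <- numeric(nn)
  nuTrend <- if (!is.null(trend)) {
    troot <- ages[n + 1L]
    function(t) trend$nu_inf + trend$amplitude * exp(-(troot - t) / trend$tau)
  } else NULL
  if (clock@kind == "acln") {
    rates[n + 1L] <- if (is.null(nuTrend)) clock@rootRate else
      nuTrend(ages[n + 1L])
    # preorder walk
    stack <- n + 1L
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (j in kids[[p]]) {
        dt <- ages[p] - ages[j]
        drift <- if (is.null(nuTrend)) -clock@sigma2 * dt / 2 else
          log(nuTrend(ages[j])) - log(nuTrend(ages[p]))
        rates[j] <- exp(log(rates[p]) + drift +
                        rnorm(1, 0, sqrt(clock@sigma2 * dt)))
        if (j > n) stack <- c(stack, j)
      }
    }
  } else {
    rates[] <- clock@rootRate *
      rgamma(nn, shape = clock@shape, rate = clock@shape)
    rates[n + 1L] <- clock@rootRate
  }
  out <- tree
  nodeRates(out) <- rates
  L <- .edgeLengths(out, branchRates = if (clock@kind == "acln") "mean" else "node")
  list(tree = out,
       truth = data.frame(node = seq_len(nn), age = ages, rate = rates,
                          expected_subs = L))
}

#' Forward-simulate a protein alignment along a dated, rated tree
#'
#' Root states are drawn from the model's equilibrium frequencies; each
#' site draws one discrete-gamma category that applies along the whole
#' tree, and each branch evolves the site through
#' `P(branch_rate * dt * gamma_c)`.
#'
#' @param tree a [TimeTree-class] with ages and rates.
#' @param model a [SubstitutionModel-class].
#' @param nSites number of alignment columns.
#' @param seed mandatory RNG seed.
#' @param branchRates `"mean"` or `"node"` (see [logLikelihood()]).
#' @return A [ProteinAlignment-class] with the tree's tip names.
#' @export
simulateAlignment <- function(tree, model, nSites, seed,
                              branchRates = c("mean", "node")) {
  branchRates <- match.arg(branchRates)
  set.seed(seed)
  phy <- tree@phylo
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  L <- .edgeLengths(tree, branchRates = branchRates)
  e <- .eigenQ(model)
  catr <- gammaCategoryRates(model@gammaShape, model@nCategories)
  siteCat <- sample.int(model@nCategories, nSites, replace = TRUE)
  pmat <- function(d) {
    P <- e$U %*% diag(exp(e$lambda * d)) %*% e$Uinv
    P[P < 0] <- 0
    P / rowSums(P)
  }
  states <- matrix(0L, nn, nSites)
  states[n + 1L, ] <- sample.int(20L, nSites, replace = TRUE,
                                 prob = model@frequencies)
  kids <- .childrenList(phy)
  stack <- n + 1L
  while (length(stack)) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (j in kids[[p]]) {
      for (cc in seq_len(model@nCategories)) {
        idx <- which(siteCat == cc)
        if (!length(idx)) next
        P <- pmat(L[j] * catr[cc])
        for (s in unique(states[p, idx])) {
          here <- idx[states[p, idx] == s]
          states[j, here] <- sample.int(20L, length(here), replace = TRUE,
                                        prob = P[s, ])
        }
      }
      if (j > n) stack <- c(stack, j)
    }
  }
  aa <- aminoAcids()
  rows <- vapply(seq_len(n), function(i)
    paste(aa[states[i, ]], collapse = ""), character(1))
  ProteinAlignment(phy$tip.label, rows)
}

#' Generate a synthetic identity-versus-time pair table
#'
#' Emulates the identity-decay layout: divergence times uniform on
#' `timeRange`, identity `intercept + slope * t + Normal(0, noiseSd)`
#' clipped to `[0, 100]`. The default slope of -8 %/Ga (0.8% per 100 Ma)
#' emulates the observed just-under-1%-per-100-Ma decay of reaction-center
#' proteins since the Proterozoic.
#'
#' @param nPairs number of pairs (>= 2).
#' @param slope percent identity per Ga (negative for decay).
#' @param intercept percent identity at time 0.
#' @param noiseSd Gaussian noise sd in percent.
#' @param timeRange length-2 range of divergence times in Ga.
#' @param seed mandatory RNG seed.
#' @return data.frame with `label_a`, `label_b`, `divergence_time_Ga`,
#'   `identity`; the generating parameters are attached as the `truth`
#'   attribute.
#' @export
generateIdentityPairs <- function(nPairs = 23, slope = -8, intercept = 100,
                                  noiseSd = 0.3, timeRange = c(0.05, 2),
                                  seed) {
  stopifnot(nPairs >= 2)
  set.seed(seed)
  t <- runif(nPairs, timeRange[1], timeRange[2])
  y <- pmin(100, pmax(0, intercept + slope * t + rnorm(nPairs, 0, noiseSd)))
  out <- data.frame(label_a = sprintf("sp%02d_a", seq_len(nPairs)),
                    label_b = sprintf("sp%02d_b", seq_len(nPairs)),
                    divergence_time_Ga = t, identity = y)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             noiseSd = noiseSd)
  out
}

# ---------------------------------------------------------------------
# A deterministic 74-taxon chronogram shaped like the reaction-center
# protein phylogeny: an oxygenic branch (D1 groups G0..G4 + D2, with
# eukaryote tips inside G4 D1 and D2 for cross-calibration) and an
# anoxygenic branch (L and M). Key nodes carry fixed anchor ages; the
# remaining internal ages are interpolated between their anchored
# neighbours, giving a valid chronogram out of the box.

.euk_names <- c("cyanidium", "galdieria", "porphyra", "phaeodactylum",
                "thalassiosira", "marchantia", "cycas", "amborella",
                "arabidopsis", "populus")

.eukSubtree <- function(prefix) {
  p <- function(x) paste0(prefix, x)
  sprintf("((%s,%s),(%s,((%s,%s),(%s,(%s,(%s,(%s,%s)))))))",
          p("cyanidium"), p("galdieria"), p("porphyra"), p("phaeodactylum"),
          p("thalassiosira"), p("marchantia"), p("cycas"), p("amborella"),
          p("arabidopsis"), p("populus"))
}

.balanced <- function(labels) {
  if (length(labels) == 1L) return(labels)
  k <- ceiling(length(labels) / 2)
  sprintf("(%s,%s)", .balanced(labels[1:k]),
          .balanced(labels[(k + 1L):length(labels)]))
}

#' Reaction-center-shaped synthetic chronogram with labelled clades
#'
#' A fixed 74-taxon rooted topology emulating the Type II reaction-center
#' protein family: the oxygenic branch with D1 groups G0/G1/G2 (atypical),
#' G3 (microaerobic) and G4 (dominant, containing cyanobacterial and
#' eukaryote tips) plus a D2 clade, and the anoxygenic branch with L and M
#' clades. Anchor nodes (root, the D1/D2 duplication `D0`, the L/M
#' ancestor `K`, the ancestral standard D1, crown-Cyanobacteria points,
#' the eukaryote ladders) carry fixed ages; other internal ages are
#' deterministically interpolated. Table-5-style calibrations for this
#' fixture ship as `table5_calibration1.txt` / `table5_calibration2.txt`
#' under `inst/extdata` (synthetic clade mapping).
#'
#' @return List with `tree` (a [TimeTree-class]) and `clades`, a named
#'   list of tip sets: `D0`, `standardD1`, `group4D1`, `D2`, `L`, `M`,
#'   `oxygenic`, `anoxygenic`, `group4baseline`.
#' @export
reactionCenterFixture <- function() {
  g0 <- paste0("G0_D1_", 1:3)
  g1 <- paste0("G1_D1_", 1:3)
  g2 <- paste0("G2_D1_", 1:4)
  g3 <- paste0("G3_D1_", 1:6)
  g4cy <- paste0("G4_D1_", c("gloeobacter", "pseudanabaena", "pleurocapsa",
                             "chroococcidiopsis", "nostoc", "anabaena",
                             "synechocystis", "prochlorococcus"))
  g4euk <- paste0("euk_D1_", .euk_names)
  d2cy <- paste0("D2_", c("gloeobacter", "pseudanabaena", "nostoc",
                          "synechocystis", "thermosynechococcus",
                          "prochlorococcus"))
  d2euk <- paste0("euk_D2_", .euk_names)
  lt <- paste0("L_", 1:12)
  mt <- paste0("M_", 1:12)

  g4 <- sprintf("(%s,(%s,((%s,%s),((%s,%s),(%s,(%s,%s))))))",
                "G4_D1_gloeobacter", "G4_D1_pseudanabaena",
                "G4_D1_pleurocapsa", "G4_D1_chroococcidiopsis",
                "G4_D1_nostoc", "G4_D1_anabaena", "G4_D1_synechocystis",
                "G4_D1_prochlorococcus", .eukSubtree("euk_D1_"))
  d2 <- sprintf("(%s,(%s,((%s,%s),(%s,(%s,%s)))))",
                "D2_gloeobacter", "D2_pseudanabaena", "D2_nostoc",
                "D2_synechocystis", "D2_thermosynechococcus",
                "D2_prochlorococcus", .eukSubtree("euk_D2_"))
  d1 <- sprintf("(%s,(%s,(%s,(%s,%s))))", .balanced(g0), .balanced(g1),
                .balanced(g2), .balanced(g3), g4)
  nwk <- sprintf("((%s,%s),(%s,%s));", d1, d2, .balanced(lt), .balanced(mt))

  phy <- ape::read.tree(text = nwk)
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  # height = max edges to a tip below; used to interpolate unanchored ages
  kids <- .childrenList(phy)
  height <- numeric(nn)
  post <- rev(.preorderNodes(phy))
  for (j in post)
    height[j] <- if (j <= n) 0 else 1 + max(height[kids[[j]]])

  mr <- function(tips) {
    idx <- match(tips, phy$tip.label)
    if (length(idx) == 1L) idx else ape::getMRCA(phy, idx)
  }
  anchors <- numeric(nn)
  setA <- function(tips, age) anchors[mr(tips)] <<- age
  d1all <- c(g0, g1, g2, g3, g4cy, g4euk)
  setA(c(d1all, d2cy, d2euk, lt, mt), 3.60)                 # root II
  setA(c(d1all, d2cy, d2euk), 3.30)                         # D0
  setA(c(lt, mt), 2.90)                                     # K
  setA(d1all, 3.10)
  setA(c(g1, g2, g3, g4cy, g4euk), 2.95)
  setA(c(g2, g3, g4cy, g4euk), 2.80)
  setA(c(g3, g4cy, g4euk), 2.55)                            # ancestral standard D1
  setA(c(g4cy, g4euk), 2.48)                                # crown cyanobacteria (D1)
  setA(c(d2cy, d2euk), 2.48)                                # crown cyanobacteria (D2)
  setA(c(setdiff(g4cy, "G4_D1_gloeobacter"), g4euk), 2.10)  # post-gloeobacter D1
  setA(c("G4_D1_pleurocapsa", "G4_D1_chroococcidiopsis"), 1.75)
  setA(c("G4_D1_nostoc", "G4_D1_anabaena"), 1.70)
  for (pre in c("euk_D1_", "euk_D2_")) {
    p <- function(x) paste0(pre, x)
    setA(p(.euk_names), 1.30)
    setA(p(c("porphyra", "phaeodactylum", "thalassiosira", "marchantia",
             "cycas", "amborella", "arabidopsis", "populus")), 0.90)
    setA(p(c("phaeodactylum", "thalassiosira")), 0.25)
    setA(p(c("marchantia", "cycas", "amborella", "arabidopsis", "populus")),
         0.55)
    setA(p(c("cycas", "amborella", "arabidopsis", "populus")), 0.34)
    setA(p(c("amborella", "arabidopsis", "populus")), 0.19)
    setA(p(c("arabidopsis", "populus")), 0.10)
  }
  setA(lt, 1.10)
  setA(mt, 1.10)

  # deepest anchor below each node, to keep interpolation consistent
  maxAnchorBelow <- numeric(nn)
  for (j in post)
    maxAnchorBelow[j] <- if (j <= n) 0 else
      max(anchors[kids[[j]]], maxAnchorBelow[kids[[j]]])
  ages <- numeric(nn)
  assign_age <- function(j, parentAge) {
    if (j <= n) { ages[j] <<- 0; return(invisible()) }
    a <- if (anchors[j] > 0) anchors[j] else
      max(parentAge * height[j] / (height[j] + 1), 1.05 * maxAnchorBelow[j])
    a <- min(a, 0.98 * parentAge)
    ages[j] <<- a
    for (k in kids[[j]]) assign_age(k, a)
  }
  rootNode <- n + 1L
  ages[rootNode] <- anchors[rootNode]
  for (k in kids[[rootNode]]) assign_age(k, ages[rootNode])

  tree <- TimeTree(phy, ages)
  list(tree = tree,
       clades = list(
         D0 = c(d1all, d2cy, d2euk),
         standardD1 = c(g3, g4cy, g4euk),
         group4D1 = c(g4cy, g4euk),
         D2 = c(d2cy, d2euk),
         L = lt, M = mt,
         oxygenic = c(d1all, d2cy, d2euk),
         anoxygenic = c(lt, mt),
         group4baseline = list(group4D1 = c(g4cy, g4euk),
                               D2 = c(d2cy, d2euk))))
}

# preorder node ids (root first)
.preorderNodes <- function(phy) {
  n <- length(phy$tip.label)
  kids <- .childrenList(phy)
  out <- integer(0)
  stack <- n + 1L
  while (length(stack)) {
    j <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, j)
    if (j > n) stack <- c(stack, kids[[j]])
  }
  out
}
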