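#' Read a chronogram from Newick
#'
#' Accepts plain Newick (branch lengths interpreted as durations in Ga) or
#' the annotated dialect written by [writeAnnotatedTree()], in which nodes
#' carry square-bracket comments `[&age=...,rate=...]` before the branch
#' length. Under the contemporaneous-tips contract all root-to-tip path
#' lengths must agree, node ages are reconstructed so tips sit at 0, and
#' non-ultrametric input is rejected.
#'
#' @param path a file path, or a Newick string (detected by a terminal
#'   `;`).
#' @param tol tolerance (Ga) for the equal root-to-tip path check.
#' @return A [TimeTree-class]; credible intervals, when annotated, are
#'   attached as a two-column `ci` attribute.
#' @examples
#' tr <- readTimeTree("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
#' rootAge(tr)
#' @export
readTimeTree <- function(path, tol = 1e-6) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else
    paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\s", "", txt)
  # pull out [&...] annotations, leaving numbered sentinels as node labels
  ann <- character(0)
  repeat {
    m <- regexpr("\\[&[^]]*\\]", txt)
    if (m == -1L) break
    ann <- c(ann, substr(txt, m + 2L, m + attr(m, "match.length") - 2L))
    txt <- sub("\\[&[^]]*\\]", sprintf("__ann%d", length(ann)), txt)
  }
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) || is.null(phy$edge) || length(phy$tip.label) < 2L)
    stop("topology error: could not parse a rooted tree with >= 2 tips")
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("topology error: tree must be rooted and strictly bifurcating")

  strip <- function(lab) {
    idx <- rep(NA_integer_, length(lab))
    hit <- regexpr("__ann([0-9]+)$", lab)
    has <- hit > 0L
    idx[has] <- as.integer(sub("^.*__ann([0-9]+)$", "\\1", lab[has]))
    list(lab = sub("__ann[0-9]+$", "", lab), idx = idx)
  }
  tl <- strip(phy$tip.label)
  phy$tip.label <- tl$lab
  nl <- if (!is.null(phy$node.label)) strip(phy$node.label) else
    list(lab = NULL, idx = rep(NA_integer_, phy$Nnode))
  if (!is.null(nl$lab)) phy$node.label <- nl$lab
  annIdx <- c(tl$idx, nl$idx)

  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  parseAnn <- function(s) {
    kv <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
    names(vals) <- vapply(kv, `[`, character(1), 1)
    vals
  }
  ages <- rep(NA_real_, nn); rates <- rep(NA_real_, nn)
  ci <- matrix(NA_real_, nn, 2, dimnames = list(NULL, c("low", "high")))
  for (j in seq_len(nn)) {
    if (is.na(annIdx[j])) next
    v <- parseAnn(ann[annIdx[j]])
    if ("age" %in% names(v)) ages[j] <- v[["age"]]
    if ("rate" %in% names(v)) rates[j] <- v[["rate"]]
    if ("ci_low" %in% names(v)) ci[j, 1] <- v[["ci_low"]]
    if ("ci_high" %in% names(v)) ci[j, 2] <- v[["ci_high"]]
  }

  internal <- (n + 1L):nn
  if (all(!is.na(ages[internal]))) {
    ages[seq_len(n)] <- 0
  } else {
    if (is.null(phy$edge.length))
      stop("age error: no branch lengths and no age annotations")
    if (any(phy$edge.length < 0))
      stop("age error: negative branch duration")
    depth <- ape::node.depth.edgelength(phy)
    tipd <- depth[seq_len(n)]
    if (diff(range(tipd)) > tol)
      stop("age error: unequal root-to-tip path lengths (",
           sprintf("%.6g vs %.6g", min(tipd), max(tipd)),
           ") violate the contemporaneous-tips contract")
    ages <- max(tipd) - depth
    ages[seq_len(n)] <- 0
  }
  tt <- TimeTree(phy, ages,
                 rates = if (all(!is.na(rates))) rates else numeric(0))
  if (any(!is.na(ci))) attr(tt, "ci") <- ci
  tt
}

#' Write a chronogram as annotated Newick
#'
#' Every node carries a `[&age=...]` comment (ages at full precision so
#' that read-after-write reproduces them to 1e-9 Ga); nodes with rates add
#' `rate=` at 6 significant digits, and an optional credible-interval
#' matrix adds `ci_low`/`ci_high`. Branch lengths are the age differences.
#'
#' @param tree a [TimeTree-class] with ages (rates optional).
#' @param path output file.
#' @param ci optional two-column matrix of per-node interval bounds.
#' @return `path`, invisibly.
#' @export
writeAnnotatedTree <- function(tree, path, ci = NULL) {
  phy <- tree@phylo
  ages <- tree@ages
  if (!length(ages)) stop("contract error: tree has no ages")
  rates <- tree@rates
  n <- length(phy$tip.label)
  kids <- .childrenList(phy)
  lab <- function(j) {
    if (j <= n) return(phy$tip.label[j])
    if (!is.null(phy$node.label)) {
      l <- phy$node.label[j - n]
      if (!is.na(l) && nzchar(l)) return(l)
    }
    ""
  }
  annot <- function(j) {
    parts <- sprintf("age=%.12g", ages[j])
    if (length(rates)) parts <- c(parts, sprintf("rate=%.6g", rates[j]))
    if (!is.null(ci) && !anyNA(ci[j, ]))
      parts <- c(parts, sprintf("ci_low=%.12g", ci[j, 1]),
                 sprintf("ci_high=%.12g", ci[j, 2]))
    sprintf("[&%s]", paste(parts, collapse = ","))
  }
  build <- function(j, parentAge) {
    core <- if (j <= n) lab(j) else
      sprintf("(%s)%s", paste(vapply(kids[[j]], build, character(1),
                                     parentAge = ages[j]), collapse = ","),
              lab(j))
    bl <- if (is.na(parentAge)) "" else sprintf(":%.12g", parentAge - ages[j])
    paste0(core, annot(j), bl)
  }
  out <- paste0(build(n + 1L, NA_real_), ";")
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("I/O error: cannot open '", path, "' for writing"))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

# children of each node, indexed by ape node number
.childrenList <- function(phy) {
  nn <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  kids
}

# parent of each node (NA at root)
.parentVec <- function(phy) {
  nn <- length(phy$tip.label) + phy$Nnode
  par <- rep(NA_integer_, nn)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

#' Resolve a clade to its most recent common ancestor node
#'
#' @param tree a [TimeTree-class].
#' @param tips character vector of tip labels (a single tip resolves to
#'   itself).
#' @param requireMonophyly error unless the MRCA's descendants are exactly
#'   `tips` (used for calibration placement).
#' @return The ape node number of the MRCA.
#' @export
mrcaNode <- function(tree, tips, requireMonophyly = FALSE) {
  phy <- tree@phylo
  miss <- setdiff(tips, phy$tip.label)
  if (length(miss))
    stop("clade-resolution error: unknown tips ", paste(miss, collapse = ", "))
  idx <- match(tips, phy$tip.label)
  node <- if (length(idx) == 1L) idx else ape::getMRCA(phy, idx)
  if (requireMonophyly) {
    desc <- cladeTips(tree, node)
    if (!setequal(desc, tips))
      stop("clade-resolution error: tips ", paste(tips, collapse = ","),
           " are not monophyletic in the fixed topology")
  }
  node
}

#' Tips descended from a node
#' @param tree a [TimeTree-class].
#' @param node an ape node number.
#' @return Character vector of descendant tip labels.
#' @export
cladeTips <- function(tree, node) {
  phy <- tree@phylo
  n <- length(phy$tip.label)
  if (node <= n) return(phy$tip.label[node])
  kids <- .childrenList(phy)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    j <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (j <= n) out <- c(out, j) else stack <- c(stack, kids[[j]])
  }
  phy$tip.label[out]
}

# short label for an internal node: sorted first letters of a few tips
.nodeLabel <- function(tree, node) {
  tp <- sort(cladeTips(tree, node))
  if (length(tp) > 3L)
    sprintf("%s+%d", paste(tp[1:2], collapse = "|"), length(tp) - 2L)
  else paste(tp, collapse = "|")
}
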