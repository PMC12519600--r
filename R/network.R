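#' Latent-component similarity matrices
#'
#' The standard relevance-association measure for PLS-family models:
#' the similarity of variable j with class k is
#' `sum_h cor(X_j, t_h) * cor(Y_k, t_h)` over the model's components
#' (X_j the scaled training column, Y_k the centered class dummy, t_h the
#' training scores), and variable-variable similarity replaces the class
#' profile by the second variable's correlation profile. Only variables
#' with a nonzero loading on at least one component enter. Constant
#' selected columns get similarity 0 with a flag.
#'
#' @param model a fitted [SplsdaModel-class].
#' @param X,y the training data the model was fitted on.
#' @return list: `varClass` (nodes x 2), `varVar` (nodes x nodes,
#'   symmetric), `pearsonClass` (plain Pearson correlation of each node
#'   with the case indicator), `flagged` (constant node names).
#' @export
similarityMatrix <- function(model, X, y) {
  X <- as.matrix(X)
  yf <- factor(y, levels = model@labels)
  keep <- rowSums(model@loadingsX != 0) > 0
  nodes <- rownames(model@loadingsX)[keep]
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, model@xCenter[keep], `-`),
              2, model@xScale[keep], `/`)
  Yd <- cbind(as.numeric(yf == model@labels[1]),
              as.numeric(yf == model@labels[2]))
  Yc <- scale(Yd, scale = FALSE)
  Tm <- model@scores
  H <- model@ncomp
  flagged <- nodes[apply(Xs, 2, sd) == 0]
  corX <- suppressWarnings(cor(Xs, Tm))     # nodes x H
  corX[is.na(corX)] <- 0                    # constant columns -> 0, flagged
  corY <- cor(Yc, Tm)                       # 2 x H
  varClass <- corX %*% t(corY)
  dimnames(varClass) <- list(nodes, model@labels)
  varVar <- tcrossprod(corX)
  dimnames(varVar) <- list(nodes, nodes)
  list(varClass = varClass, varVar = varVar,
       pearsonClass = drop(suppressWarnings(cor(X[, keep, drop = FALSE],
                                                as.numeric(yf) - 1))),
       flagged = flagged)
}

#' Build a thresholded relevance network
#'
#' Edges connect variables to class nodes and to each other wherever
#' `|similarity| >= threshold`; isolated nodes stay in the node table but
#' carry no edges.
#'
#' @param sim list from [similarityMatrix()] (or matching `varClass`,
#'   `varVar`, optional `pearsonClass`).
#' @param threshold minimum absolute similarity for an edge, default 0.23.
#' @return a [RelevanceNetwork-class].
#' @export
buildNetwork <- function(sim, threshold = 0.23) {
  vc <- sim$varClass
  vv <- sim$varVar
  nodes <- rownames(vc)
  classNodes <- colnames(vc)
  edges <- list()
  hit <- which(abs(vc) >= threshold, arr.ind = TRUE)
  if (nrow(hit)) {
    edges[[1]] <- data.frame(nodeA = nodes[hit[, 1]],
                             nodeB = classNodes[hit[, 2]],
                             similarity = vc[hit])
  }
  up <- which(upper.tri(vv) & abs(vv) >= threshold, arr.ind = TRUE)
  if (nrow(up)) {
    edges[[length(edges) + 1L]] <- data.frame(nodeA = nodes[up[, 1]],
                                              nodeB = nodes[up[, 2]],
                                              similarity = vv[up])
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(nodeA = character(), nodeB = character(),
               similarity = numeric())
  edges$sign <- sign(edges$similarity)
  edges <- edges[order(-abs(edges$similarity), edges$nodeA, edges$nodeB), ]
  rownames(edges) <- NULL
  pc <- sim$pearsonClass %||% rep(NA_real_, length(nodes))
  new("RelevanceNetwork", nodes = nodes, classNodes = classNodes,
      varClass = vc, varVar = vv, pearsonClass = pc,
      threshold = threshold, edges = edges)
}

#' Rank variables by association with the case class
#'
#' Variables are sorted by decreasing absolute similarity to the case
#' node; ties break alphabetically for determinism. The signed similarity
#' is reported, so negative values read as case-protective.
#'
#' @param network a [RelevanceNetwork-class].
#' @param k number of variables to report (default 10).
#' @return data.frame: rank, variable, similarity (signed, to the case
#'   class), pearson (plain correlation with the case indicator).
#' @export
rankTopVariables <- function(network, k = 10L) {
  simCase <- network@varClass[, 2]
  if (k > length(simCase)) stopf("k = %d exceeds node count %d", k,
                                 length(simCase))
  ord <- order(-abs(simCase), names(simCase))
  top <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), variable = names(simCase)[top],
             similarity = unname(simCase[top]),
             pearson = unname(network@pearsonClass[top]))
}

#' Export the network
#'
#' `writeEdgesTsv()` writes the thresholded edge list; `writeNetworkGraphML()`
#' writes the graph (class nodes flagged by a `type` attribute, signed
#' similarity as edge weight) in GraphML via igraph.
#'
#' @param network a [RelevanceNetwork-class].
#' @param path output path.
#' @export
writeEdgesTsv <- function(network, path) {
  utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgesTsv
#' @export
writeNetworkGraphML <- function(network, path) {
  vdf <- data.frame(name = c(network@nodes, network@classNodes),
                    type = c(rep("variable", length(network@nodes)),
                             rep("class", 2)))
  e <- network@edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$nodeA, to = e$nodeB,
               weight = e$similarity, sign = e$sign),
    directed = FALSE, vertices = vdf)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
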