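## Spearman correlation networks across RNAs, mobile RNAs and metabolites.

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; ties receive their mean rank.
#' Requires at least 3 finite paired observations; a constant vector has no
#' rank ordering and yields NA with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho in [-1, 1], or NA for a constant input.
#' @examples
#' spearmanRho(1:4, c(8, 6, 4, 2))   # -1
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y)) stop("vectors differ in length")
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 paired finite observations")
    if (sd(x) == 0 || sd(y) == 0) {
        warning("constant vector: Spearman correlation undefined")
        return(NA_real_)
    }
    cor(x, y, method = "spearman")
}

#' Build a typed Spearman correlation network
#'
#' Computes all pairwise Spearman correlations across node profiles and
#' retains edges with |rho| >= \code{rho_min} in canonical (node_a <
#' node_b) order. Node types (rna, mobile_rna, metabolite) tag both edge
#' endpoints for downstream styling.
#'
#' @param profiles nodes x samples numeric matrix (rownames = node ids).
#' @param node_types character vector (per row of \code{profiles}) with
#'   values in rna / mobile_rna / metabolite.
#' @param rho_min edge retention threshold on |rho|.
#' @return A list with \code{edges} (node_a, node_b, rho, sign, type_a,
#'   type_b), \code{nodes} (id, type, degree) and \code{type_counts}.
#' @export
buildNetwork <- function(profiles, node_types, rho_min = 0.9) {
    profiles <- as.matrix(profiles)
    if (nrow(profiles) < 2) stop("need at least 2 nodes")
    if (is.null(rownames(profiles))) stop("profiles must have rownames")
    if (length(node_types) != nrow(profiles))
        stop("node_types must match the profile rows")
    if (!all(node_types %in% c("rna", "mobile_rna", "metabolite")))
        stop("node types must be rna, mobile_rna or metabolite")
    if (ncol(profiles) < 3) stop("profiles need at least 3 samples")
    suppressWarnings(
        R <- cor(t(profiles), method = "spearman",
                 use = "pairwise.complete.obs"))
    ids <- rownames(profiles)
    idx <- which(upper.tri(R) & !is.na(R) & abs(R) >= rho_min,
                 arr.ind = TRUE)
    edges <- data.frame(node_a = character(), node_b = character(),
                        rho = numeric(), sign = character(),
                        type_a = character(), type_b = character(),
                        stringsAsFactors = FALSE)
    if (nrow(idx)) {
        a <- ids[idx[, 1]]; b <- ids[idx[, 2]]
        ta <- node_types[idx[, 1]]; tb <- node_types[idx[, 2]]
        swap <- a > b
        tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
        tmp <- ta[swap]; ta[swap] <- tb[swap]; tb[swap] <- tmp
        rho <- R[idx]
        edges <- data.frame(node_a = a, node_b = b, rho = rho,
                            sign = ifelse(rho >= 0, "+", "-"),
                            type_a = ta, type_b = tb,
                            stringsAsFactors = FALSE)
        edges <- edges[order(edges$node_a, edges$node_b), ]
        rownames(edges) <- NULL
    }
    degree <- setNames(integer(length(ids)), ids)
    if (nrow(edges)) {
        tab <- table(c(edges$node_a, edges$node_b))
        degree[names(tab)] <- as.integer(tab)
    }
    list(edges = edges,
         nodes = data.frame(id = ids, type = node_types,
                            degree = unname(degree),
                            stringsAsFactors = FALSE),
         type_counts = table(node_types))
}

#' Restrict a network to pathway-tagged nodes
#'
#' Retains edges whose two endpoints both carry one of the requested
#' pathway tags (e.g. photosynthesis or carbon metabolism); node typing is
#' preserved.
#'
#' @param network a network from \code{\link{buildNetwork}}.
#' @param membership data.frame with columns \code{node} and
#'   \code{pathway}.
#' @param pathways pathway tags to keep.
#' @return The filtered network (same shape as \code{\link{buildNetwork}}).
#' @export
pathwaySubnetwork <- function(network, membership, pathways) {
    known <- unique(membership$pathway)
    unknown <- setdiff(pathways, known)
    if (length(unknown))
        stop("unknown pathway tag(s): ", paste(unknown, collapse = ", "),
             "; available: ", paste(sort(known), collapse = ", "))
    tagged <- unique(membership$node[membership$pathway %in% pathways])
    edges <- network$edges
    keep <- edges$node_a %in% tagged & edges$node_b %in% tagged
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
    nodes <- network$nodes[network$nodes$id %in% tagged, , drop = FALSE]
    degree <- setNames(integer(nrow(nodes)), nodes$id)
    if (nrow(edges)) {
        tab <- table(c(edges$node_a, edges$node_b))
        degree[names(tab)] <- as.integer(tab)
    }
    nodes$degree <- unname(degree[nodes$id])
    rownames(nodes) <- NULL
    list(edges = edges, nodes = nodes,
         type_counts = table(nodes$type))
}

#' Convert a network to igraph / write GraphML
#'
#' @param network a network from \code{\link{buildNetwork}}.
#' @return \code{asIgraph}: an \link[igraph]{igraph} graph with node
#'   \code{type} and edge \code{rho} attributes.
#' @export
asIgraph <- function(network) {
    igraph::graph_from_data_frame(network$edges[, c("node_a", "node_b",
                                                    "rho", "sign")],
                                  directed = FALSE,
                                  vertices = network$nodes)
}

#' @rdname asIgraph
#' @param path GraphML output path.
#' @export
writeGraphML <- function(network, path) {
    igraph::write_graph(asIgraph(network), path, format = "graphml")
    invisible(path)
}
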