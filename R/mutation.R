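## Conservation-weighted 3D mutation clustering and the conserved-contact
## network. Mutation counts are aggregated per sequence position, spread
## over the residues of the structure carrying that position (all five
## chains of a homopentamer), summed inside a 9 Angstrom sphere around
## each C-alpha, and down-weighted where conservation is low so that
## isolated or poorly conserved changes are filtered out.

#' Raw 3D mutation hits within a sphere around each residue
#'
#' `raw_hits[i]` is the sum of mutation counts over every residue whose
#' C-alpha lies within `radius` of residue i's C-alpha, the residue itself
#' included.
#'
#' @param coords N x 3 C-alpha coordinates.
#' @param counts mutation count per coordinate row (length N, >= 0).
#' @param radius sphere radius, Angstrom (default 9, the typical pairwise
#'   interaction cutoff).
#' @return numeric vector of raw hits, length N.
#' @export
sphere_hits <- function(coords, counts, radius = 9) {
  coords <- as.matrix(coords)
  if (radius <= 0) stop("sphere_hits: radius must be > 0")
  if (length(counts) != nrow(coords))
    stop("sphere_hits: counts not aligned to coordinate rows")
  if (any(counts < 0)) stop("sphere_hits: counts must be >= 0")
  D <- as.matrix(stats::dist(coords))
  as.numeric((D <= radius) %*% counts)
}

#' Weight raw hits by residue conservation
#'
#' Default linear weighting: `weighted = raw_hits * score / 9`, so a fully
#' conserved residue (grade 9) keeps its raw hits and variable residues
#' are proportionally down-weighted. The "indicator" alternative keeps
#' only residues with grade >= 8 (weight 1) and zeroes the rest.
#'
#' @param raw_hits from [sphere_hits()].
#' @param scores integer conservation grades in 1..9, aligned to
#'   `raw_hits`.
#' @param method "linear" (default) or "indicator".
#' @return weighted scores (dimensionless), same length as `raw_hits`.
#' @export
weight_by_conservation <- function(raw_hits, scores,
                                   method = c("linear", "indicator")) {
  method <- match.arg(method)
  if (length(scores) != length(raw_hits))
    stop("weight_by_conservation: scores not aligned to raw_hits")
  if (any(scores < 1 | scores > 9))
    stop("weight_by_conservation: conservation scores must be in [1, 9]")
  if (method == "linear") raw_hits * scores / 9
  else raw_hits * as.numeric(scores >= 8)
}

#' Conservation-weighted mutation clustering scan of a structure
#'
#' End-to-end scan: aggregates the allele-level mutation table per
#' position (summing counts, recording the number of distinct alleles),
#' maps positions onto every chain of the structure, computes sphere hits
#' and conservation-weighted scores.
#'
#' @param structure `structure3d` or `ca_set`.
#' @param mutations data.frame `position,allele,count` (or a CSV path).
#' @param conservation data.frame `position,score` (or a TSV path).
#' @param radius sphere radius, Angstrom.
#' @param method weighting method, see [weight_by_conservation()].
#' @return data.frame of class `mutation_scan`: one row per structure
#'   residue with `chain`, `position`, `count`, `distinct_alleles`,
#'   `conservation`, `raw_hits`, `weighted_score`.
#' @export
mutation_scan <- function(structure, mutations, conservation, radius = 9,
                          method = "linear") {
  if (is.character(mutations)) mutations <- read_mutation_csv(mutations)
  if (is.character(conservation)) conservation <- read_conservation_tsv(conservation)
  ca <- as_ca(structure)
  agg <- stats::aggregate(count ~ position, data = mutations, FUN = sum)
  nall <- stats::aggregate(allele ~ position, data = mutations,
                           FUN = function(a) length(unique(a)))
  pos <- ca$labels$resno
  counts <- agg$count[match(pos, agg$position)]
  counts[is.na(counts)] <- 0
  dall <- nall$allele[match(pos, nall$position)]
  dall[is.na(dall)] <- 0L
  cons <- conservation$score[match(pos, conservation$position)]
  if (any(is.na(cons)))
    stop("mutation_scan: conservation scores missing for some positions")
  raw <- sphere_hits(ca$coords, counts, radius = radius)
  w <- weight_by_conservation(raw, cons, method = method)
  out <- data.frame(chain = ca$labels$chain %||% "A",
                    position = pos, count = counts,
                    distinct_alleles = dall, conservation = cons,
                    raw_hits = raw, weighted_score = w,
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_scan", "data.frame")
  out
}

#' Contact network between highly conserved residues
#'
#' Nodes are residues with conservation grade >= `threshold` (default 8);
#' edges connect node pairs whose C-alphas are within `cutoff` Angstrom,
#' excluding trivial backbone neighbours (sequence separation <= 2 within
#' a chain).
#'
#' @param structure `structure3d` or `ca_set`.
#' @param conservation data.frame `position,score` or score vector aligned
#'   to residues.
#' @param threshold minimum conservation grade for a node.
#' @param cutoff contact distance cutoff, Angstrom.
#' @return list of class `contact_network`: `nodes` (data.frame
#'   chain/resno/score), `edges` (data.frame chain_i/res_i/chain_j/res_j/
#'   distance), `graph` (igraph object).
#' @export
conserved_network <- function(structure, conservation, threshold = 8,
                              cutoff = 9) {
  ca <- as_ca(structure)
  pos <- ca$labels$resno
  scores <- if (is.data.frame(conservation))
    conservation$score[match(pos, conservation$position)]
  else rep_len(conservation, length(pos))
  if (any(is.na(scores)))
    stop("conserved_network: conservation scores must cover all residues")
  keep <- which(scores >= threshold)
  nodes <- data.frame(chain = ca$labels$chain[keep], resno = pos[keep],
                      score = scores[keep], stringsAsFactors = FALSE)
  edges <- data.frame(chain_i = character(0), res_i = integer(0),
                      chain_j = character(0), res_j = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (length(keep) >= 2) {
    co <- ca$coords[keep, , drop = FALSE]
    D <- as.matrix(stats::dist(co))
    ut <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
    if (nrow(ut)) {
      i <- keep[ut[, 1]]; j <- keep[ut[, 2]]
      trivial <- ca$labels$chain[i] == ca$labels$chain[j] &
        abs(pos[i] - pos[j]) <= 2
      sel <- !trivial
      edges <- data.frame(chain_i = ca$labels$chain[i][sel],
                          res_i = pos[i][sel],
                          chain_j = ca$labels$chain[j][sel],
                          res_j = pos[j][sel],
                          distance = D[ut][sel], stringsAsFactors = FALSE)
    }
  }
  node_ids <- paste0(nodes$chain, nodes$resno)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) data.frame(from = paste0(edges$chain_i, edges$res_i),
                                to = paste0(edges$chain_j, edges$res_j),
                                weight = edges$distance) else
      data.frame(from = character(0), to = character(0),
                 weight = numeric(0)),
    directed = FALSE,
    vertices = data.frame(name = node_ids, score = nodes$score))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat("contact_network:", nrow(x$nodes), "conserved residues,",
      nrow(x$edges), "contacts\n")
  invisible(x)
}
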