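## Plain-text exchange formats: mutation/conservation tables, per-residue
## score tables, network edge lists, portable mode-set containers (JSON
## header + CSV matrix), projections, free-energy grids and channel
## definitions.

#' Read / write mutation and conservation tables
#'
#' Mutation tables are CSV with columns `position,allele,count`;
#' conservation tables are TSV with columns `position,score` (integer
#' grades 1-9).
#'
#' @param path file path.
#' @name mutation_tables
#' @export
read_mutation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "allele", "count")
  if (!all(need %in% names(df)))
    stop("read_mutation_csv: expected columns ", paste(need, collapse = ","))
  df
}

#' @rdname mutation_tables
#' @export
read_conservation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "score") %in% names(df)))
    stop("read_conservation_tsv: expected columns position,score")
  df
}

#' @rdname mutation_tables
#' @param scan `mutation_scan` result.
#' @export
write_scores_csv <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a contact network as an edge-list CSV and GraphML
#'
#' @param network `contact_network`.
#' @param csv_path edge-list CSV path (NULL to skip).
#' @param graphml_path GraphML path (NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, csv_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(network, "contact_network"))
  if (!is.null(csv_path))
    utils::write.csv(network$edges, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  invisible(c(csv_path, graphml_path))
}

#' Portable mode-set serialization
#'
#' A mode set is stored as two sibling files: `<base>.json` (eigenvalues,
#' provenance, mean coordinates, residue count) and `<base>.csv` (the mode
#' matrix, 3N rows x K columns). The container is interchangeable between
#' ensemble-PCA, ED and ENM mode sets.
#'
#' @param modeset `modeset`.
#' @param base path prefix (without extension).
#' @name modeset_io
#' @export
write_modeset <- function(modeset, base) {
  stopifnot(inherits(modeset, "modeset"))
  header <- list(provenance = modeset$provenance,
                 n_res = modeset$n_res,
                 eigenvalues = modeset$eigenvalues,
                 variance_fraction = modeset$variance_fraction,
                 mean = modeset$mean)
  jsonlite::write_json(header, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(as.data.frame(modeset$modes), paste0(base, ".csv"),
                   row.names = FALSE)
  invisible(base)
}

#' @rdname modeset_io
#' @export
read_modeset <- function(base) {
  header <- jsonlite::fromJSON(paste0(base, ".json"))
  modes <- as.matrix(utils::read.csv(paste0(base, ".csv")))
  dimnames(modes) <- NULL
  structure(list(modes = modes,
                 eigenvalues = as.numeric(header$eigenvalues),
                 variance_fraction = as.numeric(header$variance_fraction),
                 mean = if (is.null(header$mean)) NULL
                 else as.numeric(header$mean),
                 n_res = header$n_res,
                 provenance = header$provenance),
            class = "modeset")
}

#' Write projections to CSV (`label,pc1,pc2,...`)
#' @param projections `pc_projection` data.frame.
#' @param path output path.
#' @param labels optional label column.
#' @export
write_projections_csv <- function(projections, path, labels = NULL) {
  df <- as.data.frame(projections)
  if (!is.null(labels)) df <- cbind(label = labels, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a free-energy grid to CSV (long format: pc1, pc2, count, dg_kt,
#' dg_kjmol; masked bins have empty dG fields)
#' @param fel `fel_grid`.
#' @param path output path.
#' @export
write_fel_csv <- function(fel, path) {
  stopifnot(inherits(fel, "fel_grid"))
  grid <- expand.grid(ix = seq_along(fel$x_mid), iy = seq_along(fel$y_mid))
  df <- data.frame(pc1 = fel$x_mid[grid$ix], pc2 = fel$y_mid[grid$iy],
                   count = fel$counts[cbind(grid$ix, grid$iy)],
                   dg_kt = fel$dg_kt[cbind(grid$ix, grid$iy)],
                   dg_kjmol = fel$dg_kjmol[cbind(grid$ix, grid$iy)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a channel definition as JSON
#' @param channel_def `channel_def`.
#' @param path file path.
#' @name channel_def_io
#' @export
write_channel_def <- function(channel_def, path) {
  jsonlite::write_json(unclass(channel_def), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname channel_def_io
#' @export
read_channel_def <- function(path) {
  cd <- jsonlite::fromJSON(path)
  cd <- lapply(cd, function(v) if (is.numeric(v)) as.integer(v) else v)
  class(cd) <- "channel_def"
  cd
}

#' Write a pore profile to CSV (`z,radius,cx,cy`)
#' @param profile `pore_profile`.
#' @param path output path.
#' @export
write_pore_csv <- function(profile, path) {
  stopifnot(inherits(profile, "pore_profile"))
  utils::write.csv(profile$profile, path, row.names = FALSE)
  invisible(path)
}
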