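# File formats: newline-delimited JSON molecules, TSV edge/pair/prediction
# tables, YAML configs. All formats are plain text and diffable.

#' Write molecules to newline-delimited JSON
#'
#' One JSON object per line: \{id, atoms: \[\{element, valence, h, aromatic\}\],
#' bonds: \[\[k, m\], ...\]\} with 1-based atom indices. Degree is derived at
#' load, never stored.
#'
#' @param compounds List of `internal_graph`s or a `gog`.
#' @param path Output path.
#' @export
write_molecules <- function(compounds, path) {
  if (inherits(compounds, "gog")) compounds <- compounds$compounds
  lines <- vapply(compounds, function(g) {
    bonds <- internal_edge_matrix(g)
    jsonlite::toJSON(list(
      id = g$id,
      atoms = lapply(seq_len(n_atoms(g)), function(k) list(
        element = g$atoms$element[k],
        valence = g$atoms$valence[k],
        h = g$atoms$hydrogen_count[k],
        aromatic = g$atoms$aromatic[k]
      )),
      bonds = if (NROW(bonds)) unname(lapply(seq_len(NROW(bonds)), function(r) bonds[r, ])) else list()
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read molecules from newline-delimited JSON
#'
#' Compounds with more than `max_atoms` atoms are skipped with a message
#' (mirroring the usual at-most-64-atoms dataset filter); parse errors report
#' the offending line.
#'
#' @param path Input path.
#' @param max_atoms Atom-count cap (default 64); NULL disables the filter.
#' @return List of `internal_graph`s. The number of skipped compounds is
#'   attached as attribute `n_skipped`.
#' @export
read_molecules <- function(path, max_atoms = 64L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  skipped <- 0L
  for (ln in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
                    error = function(e) {
                      abort(sprintf("molecule parse error at line %d: %s", ln, conditionMessage(e)),
                            class = "gognn_parse_error")
                    })
    n <- length(rec$atoms)
    if (!is.null(max_atoms) && n > max_atoms) {
      skipped <- skipped + 1L
      next
    }
    atoms <- data.frame(
      element = vapply(rec$atoms, function(a) a$element, character(1)),
      valence = vapply(rec$atoms, function(a) as.integer(a$valence), integer(1)),
      hydrogen_count = vapply(rec$atoms, function(a) as.integer(a$h), integer(1)),
      aromatic = vapply(rec$atoms, function(a) isTRUE(a$aromatic), logical(1)),
      stringsAsFactors = FALSE
    )
    bonds <- if (length(rec$bonds)) {
      do.call(rbind, lapply(rec$bonds, function(b) as.integer(unlist(b))))
    } else NULL
    out[[length(out) + 1L]] <- internal_graph(rec$id, atoms, bonds)
  }
  if (skipped > 0) {
    message(sprintf("skipped %d compound(s) over the %d-atom cap", skipped, max_atoms))
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Read / write external edge lists
#'
#' Two-column tab-separated compound ids; lines starting with '#' are
#' comments.
#'
#' @param path File path.
#' @return `read_edges`: a 2-column character matrix.
#' @export
read_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(matrix(character(0), ncol = 2))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) {
    abort(sprintf("edge file: expected 2 tab-separated columns at line %d", bad[1]),
          class = "gognn_parse_error")
  }
  cbind(vapply(parts, `[`, character(1), 1), vapply(parts, `[`, character(1), 2))
}

#' @param edges 2-column character matrix of ids.
#' @rdname read_edges
#' @export
write_edges <- function(edges, path) {
  writeLines(paste(edges[, 1], edges[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read / write labeled pair tables
#'
#' Tab-separated id_i, id_j, label with a header line.
#'
#' @param path File path.
#' @return `read_pairs`: tibble id_i, id_j, label.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = c("character", "character", "integer"))
  tibble::as_tibble(df)
}

#' @param pairs Tibble with id_i, id_j, label.
#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("id_i", "id_j", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write prediction scores
#'
#' Tab-separated id_i, id_j, score with a header line.
#'
#' @param predictions Tibble with id_i, id_j, score.
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions[, c("id_i", "id_j", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  tibble::as_tibble(df)
}

#' Load a GoG from molecule and edge files
#'
#' @param molecules_path Newline-delimited JSON molecules.
#' @param edges_path Two-column TSV of compound ids.
#' @param max_atoms Atom-count cap applied while loading.
#' @return A validated `gog`.
#' @export
load_gog <- function(molecules_path, edges_path, max_atoms = 64L) {
  compounds <- read_molecules(molecules_path, max_atoms = max_atoms)
  edges <- read_edges(edges_path)
  build_gog(compounds, edges)
}

#' Read / write a training config as YAML
#'
#' @param path File path.
#' @return `read_config`: a [gognn_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(gognn_config, vals)
}

#' @param config A [gognn_config()].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
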