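#' Read molecules from an SDF file (optional adapter)
#'
#' Converts a V2000 SDF file to the package's native internal-graph
#' structure via the ChemmineR toolkit (a suggested dependency). Bond types
#' are dropped, as everywhere in the package; valence is taken as the
#' bond-order sum (aromatic bonds count 1.5, rounded up), implicit hydrogens
#' as typical valence minus the bond-order sum (floored at 0), and an atom
#' is flagged aromatic when it participates in an aromatic-typed bond.
#' The adapter trusts the file; no chemistry is re-perceived.
#'
#' @param path SDF file path.
#' @param max_atoms Atom-count cap with logged skip count (default 64).
#' @return List of `internal_graph`s with attribute `n_skipped`.
#' @export
read_molecules_sdf <- function(path, max_atoms = 64L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("reading SDF requires the ChemmineR package", class = "gognn_config_error")
  }
  sdfs <- ChemmineR::read.SDFset(path)
  out <- list()
  skipped <- 0L
  for (s in seq_along(sdfs)) {
    sdf <- sdfs[[s]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    n <- nrow(ab)
    if (!is.null(max_atoms) && n > max_atoms) {
      skipped <- skipped + 1L
      next
    }
    elements <- gsub("_.*$", "", rownames(ab))
    order_sum <- numeric(n)
    aromatic <- logical(n)
    bonds <- NULL
    if (!is.null(bb) && nrow(bb) > 0) {
      a <- as.integer(bb[, 1]); b <- as.integer(bb[, 2]); ty <- as.integer(bb[, 3])
      ord <- ifelse(ty == 4, 1.5, pmin(ty, 3))
      for (r in seq_along(a)) {
        order_sum[a[r]] <- order_sum[a[r]] + ord[r]
        order_sum[b[r]] <- order_sum[b[r]] + ord[r]
        if (ty[r] == 4) aromatic[c(a[r], b[r])] <- TRUE
      }
      bonds <- cbind(a, b)
    }
    val <- pmax(typical_valence(elements), ceiling(order_sum))
    atoms <- data.frame(
      element = elements,
      valence = as.integer(val),
      hydrogen_count = as.integer(pmax(0, val - ceiling(order_sum))),
      aromatic = aromatic,
      stringsAsFactors = FALSE
    )
    id <- ChemmineR::sdfid(sdf)
    if (is.null(id) || !nzchar(id)) id <- paste0("mol", s)
    out[[length(out) + 1L]] <- internal_graph(id, atoms, bonds)
  }
  if (skipped > 0) {
    message(sprintf("skipped %d compound(s) over the %d-atom cap", skipped, max_atoms))
  }
  attr(out, "n_skipped") <- skipped
  out
}
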