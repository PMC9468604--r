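#' Pairwise Calpha RMSD matrix across structures
#'
#' For every pair of structures, matched Calpha atoms (from a sequence
#' alignment of their first chains, or from user-supplied correspondences)
#' are rigidly superposed and the minimized RMSD recorded. The result is the
#' kind of all-against-all structural-similarity matrix used to show that a
#' protein family shares one fold.
#'
#' @param structures named list of `btb_structure` objects (one chain is
#'   used per structure: the first, or set `chain` per structure by name).
#' @param maps optional list of correspondences keyed `"A|B"`, each a tibble
#'   with 0-based `index_a`, `index_b` into the chains' Calpha sequences;
#'   pairs without an entry fall back to [align_sequences()].
#' @param match,mismatch,gap alignment scheme for the fallback.
#' @return an `rmsd_matrix`: a symmetric numeric matrix (Angstrom, zero
#'   diagonal) with structure ids as dimnames. Pairs with fewer than 3
#'   matched Calpha are `NA` and reported via a warning.
#' @export
pairwise_rmsd_matrix <- function(structures, maps = NULL,
                                 match = 2, mismatch = -1, gap = -2) {
  if (is.null(names(structures)) || any(!nzchar(names(structures)))) {
    abort("structures must be a named list")
  }
  ids <- names(structures)
  k <- length(ids)
  seqs <- lapply(structures, chain_sequence)
  cas <- lapply(structures, function(s) {
    df <- as_tibble(s)
    ch <- df$chain[1]
    df <- df %>%
      filter(.data$chain == ch, .data$atom == "CA") %>%
      arrange(.data$resno)
    as.matrix(df[, c("x", "y", "z")])
  })
  out <- matrix(0, k, k, dimnames = list(ids, ids))
  skipped <- character(0)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      key <- paste(ids[i], ids[j], sep = "|")
      map <- if (!is.null(maps) && !is.null(maps[[key]])) {
        as_tibble(maps[[key]])
      } else {
        align_sequences(seqs[[i]], seqs[[j]], match, mismatch, gap)$map
      }
      if (nrow(map) < 3 ||
        max(map$index_a) >= nrow(cas[[i]]) || max(map$index_b) >= nrow(cas[[j]])) {
        skipped <- c(skipped, key)
        out[i, j] <- out[j, i] <- NA_real_
        next
      }
      r <- kabsch_superpose(
        cas[[i]][map$index_a + 1, , drop = FALSE],
        cas[[j]][map$index_b + 1, , drop = FALSE]
      )$rmsd
      out[i, j] <- out[j, i] <- r
    }
  }
  if (length(skipped) > 0) {
    warn(paste0(
      "pairs without a usable Calpha correspondence (entries set NA): ",
      paste(skipped, collapse = ", ")
    ))
  }
  class(out) <- c("rmsd_matrix", "matrix", "array")
  out
}

#' @exportS3Method generics::tidy
tidy.rmsd_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE)) %>%
    rename(structure_a = "Var1", structure_b = "Var2", rmsd = "Freq")
}

#' @exportS3Method ggplot2::autoplot
autoplot.rmsd_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$structure_a, .data$structure_b, fill = .data$rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$rmsd)), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "RMSD (Å)", direction = -1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat("<rmsd_matrix> pairwise Calpha RMSD (Å)\n")
  print(round(unclass(x), 2))
  invisible(x)
}
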