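# Compact letter display by the insert-and-absorb algorithm: start from one
# group holding every level; each significantly different pair splits the
# groups containing both; subset groups are absorbed; letters are assigned in
# order of decreasing group mean. Levels sharing a letter do not differ at the
# chosen alpha.
cld_letters <- function(means, signif_pairs) {
  n <- length(means)
  stopifnot(is.matrix(signif_pairs), nrow(signif_pairs) == n)
  groups <- list(seq_len(n))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!isTRUE(signif_pairs[i, j])) next
      new_groups <- list()
      for (g in groups) {
        if (i %in% g && j %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, i)), list(setdiff(g, j)))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      # absorb groups that are subsets of another group
      keep <- rep(TRUE, length(new_groups))
      for (a in seq_along(new_groups)) {
        for (b in seq_along(new_groups)) {
          if (a != b && keep[a] &&
              all(new_groups[[a]] %in% new_groups[[b]]) &&
              (length(new_groups[[a]]) < length(new_groups[[b]]) ||
               (length(new_groups[[a]]) == length(new_groups[[b]]) && a > b))) {
            keep[a] <- FALSE
          }
        }
      }
      groups <- unique(new_groups[keep])
    }
  }
  ord <- order(map_dbl(groups, ~ max(means[.x])), decreasing = TRUE)
  groups <- groups[ord]
  lab <- letters[seq_along(groups)]
  vapply(seq_len(n), function(l) {
    paste0(lab[map_dbl(groups, ~ as.numeric(l %in% .x)) == 1], collapse = "")
  }, character(1))
}
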