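#' Stacked relative-abundance bar plot
#'
#' One bar per sample, stacked by taxon label; the minor-taxon category, if
#' present, is drawn last. Written as SVG.
#'
#' @param rank_table a `rank_table` (typically after [merge_minor()]).
#' @param file output SVG path.
#' @return the path, invisibly.
#' @export
plot_rank_barplot <- function(rank_table, file) {
  counts <- rank_table$counts
  ra <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  n <- nrow(ra)
  cols <- grDevices::hcl.colors(max(n, 2), "Spectral")[seq_len(n)]
  if (n > 0 && grepl("^Minor ", rownames(ra)[n])) cols[n] <- "grey70"
  grDevices::svg(file, width = max(6, 1 + ncol(ra)), height = 6)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(7, 4, 2, 12), xpd = TRUE)
  graphics::barplot(ra, col = cols, border = NA, las = 2,
                    ylab = "Relative abundance",
                    main = sprintf("Composition at %s level", rank_table$rank))
  graphics::legend("topright", inset = c(-0.45, 0), legend = rownames(ra),
                   fill = cols, cex = 0.7, bty = "n")
  invisible(file)
}
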