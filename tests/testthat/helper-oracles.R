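# Independent brute force: same candidate grammar, explicit set arithmetic.
brute_force_best <- function(im, trn, uni, q_cutoff = 0.01) {
  regs <- sort(unique(trn$regulator))
  exprs <- regs
  if (length(regs) >= 2) {
    cmb <- combn(regs, 2)
    exprs <- c(exprs, paste0(cmb[1, ], "/", cmb[2, ]),
               paste0(cmb[1, ], "+", cmb[2, ]))
  }
  stats <- lapply(exprs, function(e) {
    parts <- strsplit(e, "[/+]")[[1]]
    sets <- lapply(parts, function(r) trn$gene_id[trn$regulator == r])
    genes <- if (grepl("+", e, fixed = TRUE)) Reduce(intersect, sets)
             else Reduce(union, sets)
    genes <- intersect(genes, uni)
    both <- length(intersect(im, genes))
    p <- both / length(im)
    r <- if (length(genes)) both / length(genes) else 0
    list(expr = e, n_regs = length(parts), both = both,
         f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
         pval = phyper(both - 1, length(genes), length(uni) - length(genes),
                       length(im), lower.tail = FALSE))
  })
  q <- p.adjust(vapply(stats, `[[`, 1.0, "pval"), "BH")
  ok <- which(q < q_cutoff & vapply(stats, `[[`, 1.0, "both") > 0)
  if (!length(ok)) return(NULL)
  f1 <- vapply(stats[ok], `[[`, 1.0, "f1")
  nr <- vapply(stats[ok], `[[`, 1.0, "n_regs")
  nm <- vapply(stats[ok], `[[`, "", "expr")
  stats[[ok[order(-f1, nr, nm)[1]]]]$expr
}
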