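#' Decompose a repeat block into its repeat units
#'
#' The block sequence is partitioned into consecutive windows of one unit
#' length starting at the phase (0 ... unit_len-1) that maximizes the mean
#' pairwise unit identity. Sub-unit overhang at either end is excluded from
#' the units and reported in `overhang_bp`; `copies` counts whole units.
#'
#' @param seq DNA sequence of the allele (character scalar).
#' @param span Block span on this allele, 0-based half-open `c(start, end)`.
#' @param unit_len Repeat unit length in bp.
#' @param gene_id,strain Labels carried into the result.
#' @return List of class `repeat_unit_set`: `gene_id`, `strain`, `units`
#'   (character vector), `unit_len`, `n_units`, `copies`, `overhang_bp`,
#'   `gc`, `pi`.
#' @export
decompose_units <- function(seq, span, unit_len,
                            gene_id = NA_character_,
                            strain = NA_character_) {
  unit_len <- as.integer(round(unit_len))
  stopifnot(unit_len >= 1, length(span) == 2)
  s <- as.integer(span[1]); e <- as.integer(span[2])
  block <- substring(seq, s + 1L, e)
  L <- nchar(block)
  if (L < unit_len) stop("block span shorter than one unit")

  # units at phase p; when the block is a whole number of units the two
  # sub-unit overhangs wrap into one more unit (tandem arrays are circular
  # in phase), so the recovered multiset is rotation-invariant
  units_at <- function(p) {
    n <- (L - p) %/% unit_len
    if (n < 1) return(NULL)
    units <- substring(block, p + seq(0L, n - 1L) * unit_len + 1L,
                       p + seq_len(n) * unit_len)
    if (p > 0L && L %% unit_len == 0L)
      units <- c(units, paste0(substring(block, p + n * unit_len + 1L, L),
                               substring(block, 1L, p)))
    units
  }
  best <- NULL; best_phase <- 0L; best_ident <- -1
  for (p in seq_len(unit_len) - 1L) {
    units <- units_at(p)
    if (is.null(units)) next
    ident <- if (length(units) == 1) 0 else .mean_pairwise_identity(units)
    better <- ident > best_ident + 1e-12 ||
      (abs(ident - best_ident) <= 1e-12 && !is.null(best) &&
       min(units) < min(best))  # canonical rotation on ties
    if (is.null(best) || better) {
      best <- units; best_ident <- ident; best_phase <- p
    }
  }
  n <- length(best)
  overhang <- L - n * unit_len
  if (overhang < 0) overhang <- 0L  # wrapped unit consumed both overhangs
  structure(list(
    gene_id = gene_id, strain = strain, units = best,
    unit_len = unit_len, n_units = n, copies = n,
    overhang_bp = as.integer(overhang), phase = best_phase,
    gc = gc_content(paste(best, collapse = "")),
    pi = if (n >= 2) nucleotide_diversity(best) else NA_real_),
    class = "repeat_unit_set")
}

# column-count trick: mean pairwise identity over equal-length strings
.mean_pairwise_identity <- function(units) {
  m <- .unit_matrix(units)
  n <- nrow(m)
  ident_col <- apply(m, 2, function(col) {
    col <- col[col != "N"]
    k <- length(col)
    if (k < 2) return(NA_real_)
    tab <- tabulate(factor(col, levels = c("A", "C", "G", "T")))
    sum(tab * (tab - 1) / 2) / (k * (k - 1) / 2)
  })
  mean(ident_col, na.rm = TRUE)
}

.unit_matrix <- function(units) {
  do.call(rbind, strsplit(units, "", fixed = TRUE))
}

#' Nucleotide diversity among repeat units
#'
#' Average pairwise per-site difference (the per-site average pairwise
#' diversity, pi) across all unordered unit pairs, with no finite-sample
#' correction. Sites where either unit carries N are excluded from both the
#' numerator and denominator of that pair. Units of unequal length are
#' pairwise globally aligned first (Biostrings), differences normalized by
#' the mean unit length, and the result flagged with attribute
#' `aligned = TRUE`.
#'
#' @param units Character vector of two or more DNA repeat units.
#' @return pi (numeric); `NA` with a warning if fewer than 2 units.
#' @export
nucleotide_diversity <- function(units) {
  if (length(units) < 2) {
    warning("pi undefined for fewer than 2 units")
    return(NA_real_)
  }
  lens <- nchar(units)
  if (length(unique(lens)) == 1) {
    m <- .unit_matrix(units)
    n <- length(units)
    tot <- 0; npairs <- 0L
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ok <- m[i, ] != "N" & m[j, ] != "N"
      L <- sum(ok)
      tot <- tot + if (L > 0) sum(m[i, ok] != m[j, ok]) / L else 0
      npairs <- npairs + 1L
    }
    return(tot / npairs)
  }
  # indel-containing arrays: alignment-based mode
  n <- length(units)
  tot <- 0; npairs <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    al <- Biostrings::pairwiseAlignment(units[i], units[j],
                                        type = "global")
    diffs <- Biostrings::nmismatch(al) +
      Biostrings::nindel(al)@insertion[, "WidthSum"] +
      Biostrings::nindel(al)@deletion[, "WidthSum"]
    tot <- tot + diffs / mean(c(lens[i], lens[j]))
    npairs <- npairs + 1L
  }
  structure(tot / npairs, aligned = TRUE)
}

#' GC content of a DNA sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; N is excluded from the denominator.
#'
#' @param seq DNA sequence (character scalar).
#' @return Fraction in \[0, 1\]; `NA` with a warning for an all-N sequence.
#' @export
gc_content <- function(seq) {
  stopifnot(nchar(seq) > 0)
  counts <- table(factor(strsplit(seq, "", fixed = TRUE)[[1]],
                         levels = c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0) {
    warning("GC content undefined for all-N sequence")
    return(NA_real_)
  }
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' Welch t test for GC enrichment of VNTRs over background
#'
#' Two-sample two-sided Welch (unequal variance) t test comparing VNTR GC
#' fractions with background (e.g. whole-ORF) GC fractions.
#'
#' @param vntr_gc,background_gc Numeric vectors of GC fractions, each of
#'   length at least 2.
#' @return List with `statistic`, `p_value`, `direction` (`"higher"`,
#'   `"lower"` or `"equal"`: sign of mean(vntr) - mean(background)).
#' @export
gc_enrichment_test <- function(vntr_gc, background_gc) {
  if (length(vntr_gc) < 2 || length(background_gc) < 2)
    stop("each sample must contain at least 2 values")
  if (!all(is.finite(vntr_gc)) || !all(is.finite(background_gc)))
    stop("GC fractions must be finite")
  dm <- mean(vntr_gc) - mean(background_gc)
  res <- tryCatch(
    t.test(vntr_gc, background_gc, var.equal = FALSE,
           alternative = "two.sided"),
    error = function(e) NULL)  # both samples constant
  if (is.null(res)) {
    stat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
  } else {
    stat <- unname(res$statistic); p <- res$p.value
  }
  list(statistic = stat, p_value = p,
       direction = if (dm > 0) "higher" else if (dm < 0) "lower" else "equal")
}

#' Summarize VNTR calls per gene across strains
#'
#' Per gene: min/max of unit length and copy number across strains, with
#' the reference allele included as a pseudo-strain, plus the list of
#' flagged strains. Genes with no blocks in any strain are absent from the
#' summary.
#'
#' @param calls List of calls (as from [run_scan()] / [flag_polymorphic()]):
#'   each a list with `gene_id`, `strain`, `blocks`, `flagged`.
#' @return data.frame with `gene_id`, `unit_len_min`, `unit_len_max`,
#'   `copy_min`, `copy_max`, `strains_flagged` (comma-separated).
#' @export
summarize_gene <- function(calls) {
  genes <- unique(vapply(calls, `[[`, character(1), "gene_id"))
  rows <- lapply(genes, function(g) {
    cs <- Filter(function(x) x$gene_id == g, calls)
    blocks <- do.call(rbind, lapply(cs, `[[`, "blocks"))
    if (is.null(blocks) || nrow(blocks) == 0) return(NULL)
    copies <- c(blocks$copies_a, blocks$copies_b)
    flagged <- vapply(cs, function(x) isTRUE(x$flagged), logical(1))
    data.frame(gene_id = g,
               unit_len_min = min(blocks$unit_len),
               unit_len_max = max(blocks$unit_len),
               copy_min = min(copies), copy_max = max(copies),
               strains_flagged = paste(
                 vapply(cs[flagged], `[[`, character(1), "strain"),
                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    gene_id = character(0), unit_len_min = numeric(0),
    unit_len_max = numeric(0), copy_min = numeric(0), copy_max = numeric(0),
    strains_flagged = character(0))
  rownames(out) <- NULL
  out
}
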