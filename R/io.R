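#' Write a biallelic matrix as a NEXUS character file
#'
#' Standard-datatype NEXUS with genotype coding: one row per species, each
#' character a single symbol giving the number of red copies (0, 1 or 2 for
#' a diploid); `?` marks a species with no sampled copies. This coding is
#' lossless for `(n, r)` with `n = 2`.
#'
#' @param data a [biallelic_matrix()] with per-species `n` of 0 or 2.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_character_nexus <- function(data, path) {
  if (!all(data$n %in% c(0L, 2L)))
    stop("genotype coding requires 0 or 2 copies per species")
  sym <- matrix("?", nrow(data$r), ncol(data$r))
  sym[data$n == 2L] <- as.character(data$r[data$n == 2L])
  rows <- apply(sym, 1, paste, collapse = "")
  lab <- sprintf("%-12s", data$species)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("    DIMENSIONS NTAX=%d NCHAR=%d;",
                       length(data$species), ncol(data$n)),
               "    FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=?;",
               "    MATRIX"), con)
  writeLines(paste0("        ", lab, " ", rows), con)
  writeLines(c("    ;", "END;"), con)
  invisible(path)
}

#' Read a NEXUS biallelic character matrix
#'
#' Reads a standard-datatype matrix. With `coding = "genotype"` each row is
#' one diploid species and symbols 0/1/2 count red copies (`?`/`-` =
#' missing). With `coding = "haploid"` rows are single gene copies (symbols
#' 0/1) grouped into species by the row label's prefix before a trailing
#' `_<index>`.
#'
#' @param path NEXUS file.
#' @param coding `"genotype"` or `"haploid"`.
#' @return a [biallelic_matrix()].
#' @export
read_character_nexus <- function(path, coding = c("genotype", "haploid")) {
  coding <- match.arg(coding)
  lines <- readLines(path)
  i0 <- grep("^\\s*MATRIX\\s*$", toupper(lines))
  if (!length(i0)) stop("malformed NEXUS: no MATRIX block")
  i1 <- grep("^\\s*;", lines)
  i1 <- i1[i1 > i0[1]][1]
  body <- lines[(i0[1] + 1L):(i1 - 1L)]
  body <- body[nzchar(trimws(body))]
  parts <- regmatches(body, regexec("^\\s*(\\S+)\\s+(\\S+)\\s*$", body))
  if (any(vapply(parts, length, 1L) != 3L))
    stop("malformed NEXUS matrix row")
  labels <- vapply(parts, `[`, "", 2)
  seqs <- vapply(parts, `[`, "", 3)
  chars <- do.call(rbind, strsplit(seqs, ""))
  if (length(unique(nchar(seqs))) != 1L)
    stop("inconsistent row lengths in matrix")
  if (coding == "genotype") {
    miss <- chars %in% c("?", "-")
    if (!all(chars[!miss] %in% c("0", "1", "2")))
      stop("genotype coding expects symbols 0/1/2")
    r <- matrix(0L, nrow(chars), ncol(chars))
    r[!miss] <- as.integer(chars[!miss])
    n <- matrix(2L, nrow(chars), ncol(chars))
    n[miss] <- 0L
    biallelic_matrix(labels, n, r)
  } else {
    if (!all(chars %in% c("0", "1", "?", "-")))
      stop("haploid coding expects symbols 0/1")
    species <- sub("_[0-9]+$", "", labels)
    usp <- unique(species)
    S <- length(usp)
    n <- matrix(0L, S, ncol(chars))
    r <- matrix(0L, S, ncol(chars))
    for (i in seq_along(labels)) {
      s <- match(species[i], usp)
      ok <- chars[i, ] %in% c("0", "1")
      n[s, ok] <- n[s, ok] + 1L
      r[s, ok] <- r[s, ok] + (chars[i, ok] == "1")
    }
    biallelic_matrix(usp, n, r)
  }
}

#' Recode a nucleotide alignment to biallelic characters
#'
#' Sites with more than two observed nucleotide states are removed (and
#' counted); at the remaining sites the first-observed state is labelled
#' green and any second state red (an arbitrary choice that is harmless
#' when the two state frequencies are equal). Gaps, `?` and `N` become
#' missing data.
#'
#' @param aln character matrix (gene copies x sites) of A/C/G/T symbols.
#' @param species species assignment of each row.
#' @return list with `data` (a [biallelic_matrix()]) and `n_removed`.
#' @export
nucleotide_to_biallelic <- function(aln, species) {
  stopifnot(is.matrix(aln), nrow(aln) == length(species))
  aln <- toupper(aln)
  aln[!aln %in% c("A", "C", "G", "T")] <- NA
  usp <- unique(species)
  keep <- logical(ncol(aln))
  states <- vector("list", ncol(aln))
  for (j in seq_len(ncol(aln))) {
    obs <- unique(aln[!is.na(aln[, j]), j])
    keep[j] <- length(obs) <= 2L && length(obs) >= 1L
    states[[j]] <- obs
  }
  n_removed <- sum(!keep)
  cols <- which(keep)
  S <- length(usp)
  n <- matrix(0L, S, length(cols))
  r <- matrix(0L, S, length(cols))
  for (jj in seq_along(cols)) {
    j <- cols[jj]
    green <- states[[j]][1]
    for (s in seq_len(S)) {
      rows <- which(species == usp[s])
      x <- aln[rows, j]
      n[s, jj] <- sum(!is.na(x))
      r[s, jj] <- sum(x != green, na.rm = TRUE)
    }
  }
  ok <- colSums(n) > 0
  list(data = biallelic_matrix(usp, n[, ok, drop = FALSE],
                               r[, ok, drop = FALSE]),
       n_removed = n_removed)
}

## ---------------------------------------------------------------------------
## trace logs
## ---------------------------------------------------------------------------

#' Write and read MCMC state logs
#'
#' The state log is a tab-separated table of the sampled scalars
#' (generation, lnL, lnPrior, root_height, tree_length, neu, n_heights);
#' the tree log is a NEXUS trees block with a translate table and one
#' `[&hc=...]`-annotated newick per sample. Both round-trip.
#'
#' @param trace a `phygen_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_state_log <- function(trace, path) {
  df <- trace$samples[, c("generation", "lnL", "lnPrior", "root_height",
                          "tree_length", "neu", "n_heights")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_log
#' @export
read_state_log <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' @rdname write_state_log
#' @export
write_tree_log <- function(trace, path) {
  trees <- trace$trees
  stopifnot(length(trees) >= 1)
  tips <- trees[[1]]$tips
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN TREES;", "    TRANSLATE"), con)
  writeLines(paste0("        ", seq_along(tips), " ", tips,
                    ifelse(seq_along(tips) < length(tips), ",", ";")), con)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    tr$tips <- as.character(match(tr$tips, tips))
    writeLines(sprintf("    TREE sample_%d = %s",
                       trace$samples$generation[i], write_gtree(tr)), con)
  }
  writeLines("END;", con)
  invisible(path)
}

#' @rdname write_state_log
#' @export
read_tree_log <- function(path) {
  lines <- readLines(path)
  ti <- grep("^\\s*TRANSLATE", lines)
  if (!length(ti)) stop("no TRANSLATE table in tree log")
  labs <- character(0)
  i <- ti[1] + 1L
  repeat {
    m <- regmatches(lines[i], regexec("^\\s*([0-9]+)\\s+(\\S+?)[,;]\\s*$",
                                      lines[i]))[[1]]
    if (length(m) != 3L) break
    labs[as.integer(m[2])] <- m[3]
    if (grepl(";\\s*$", lines[i])) break
    i <- i + 1L
  }
  tl <- grep("^\\s*TREE\\s", lines, ignore.case = TRUE)
  lapply(tl, function(j) {
    nw <- sub("^[^=]*=\\s*", "", lines[j])
    tr <- parse_gtree(nw)
    tr$tips <- labs[as.integer(tr$tips)]
    tr
  })
}

## ---------------------------------------------------------------------------
## YAML configuration
## ---------------------------------------------------------------------------

#' Read and write run configuration
#'
#' The YAML configuration mirrors the prior and chain settings: keys
#' `root_age` (dist/shape/mean), `alpha_tau`, `pop_size` (shape/mean),
#' `pi`, `mu`, plus optional `data`, `model` (MG or MIB), `chains`,
#' `generations`, `sample_freq`, `seed`, `variable_only` and `out`.
#'
#' @param path YAML file.
#' @return list with `prior` (a [prior_config()]) and `run` settings.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ra <- y$root_age %||% list()
  ps <- y$pop_size %||% list()
  prior <- prior_config(
    root_shape = ra$shape %||% 10,
    root_mean = ra$mean %||% 0.2,
    root_dist = ra$dist %||% "gamma",
    alpha_tau = y$alpha_tau %||% 1,
    ne_shape = ps$shape %||% 20,
    ne_mean = ps$mean %||% 0.001,
    pi = y$pi %||% 0.5,
    mu = y$mu %||% 1)
  run <- list(data = y$data %||% NULL,
              model = y$model %||% "MG",
              chains = y$chains %||% 4L,
              generations = y$generations %||% 15000L,
              sample_freq = y$sample_freq %||% 10L,
              seed = y$seed %||% 1L,
              variable_only = isTRUE(y$variable_only),
              out = y$out %||% ".")
  list(prior = prior, run = run)
}

#' @rdname read_run_config
#' @param config list as returned by [read_run_config()].
#' @export
write_run_config <- function(config, path) {
  p <- config$prior
  y <- c(list(root_age = list(dist = p$root_dist, shape = p$root_shape,
                              mean = p$root_mean),
              alpha_tau = p$alpha_tau,
              pop_size = list(shape = p$ne_shape, mean = p$ne_mean),
              pi = p$pi, mu = p$mu),
         config$run)
  yaml::write_yaml(y, path)
  invisible(path)
}
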