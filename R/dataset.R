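#' Construct a single locus
#'
#' A locus bundles an aligned set of DNA sequences with the population label
#' of each sequence, the mutation model used for its likelihood, and a
#' relative mutation-rate multiplier. Rows are ordered population 1 first,
#' then population 2.
#'
#' @param name Locus name (unique within a dataset).
#' @param alignment Character matrix of single bases, rows = sequences,
#'   columns = sites; alphabet `A`, `C`, `G`, `T` only.
#' @param pop_labels Integer vector (one per row) with values 1 or 2.
#' @param model `"HKY"` or `"IS"`.
#' @param u Positive relative mutation scale for the locus (default 1). For
#'   HKY loci branch lengths are genealogy time times `u` in expected
#'   substitutions per site; for IS loci the Poisson exposure is total branch
#'   length times `u` expected mutations for the locus.
#' @param ancestral Optional character vector (length = number of sites)
#'   giving the ancestral base at every site (IS polarization).
#' @param ancestral_row Optional row index whose sequence is used as the
#'   ancestral-state reference (alternative to `ancestral`).
#' @return An object of class `im_locus`.
#' @export
im_locus <- function(name, alignment, pop_labels, model = c("HKY", "IS"),
                     u = 1, ancestral = NULL, ancestral_row = NULL) {
  model <- match.arg(model)
  if (!is.matrix(alignment) || nrow(alignment) < 2L || ncol(alignment) < 1L)
    stop("alignment must be a matrix with >= 2 rows and >= 1 column")
  alignment <- toupper(alignment)
  bad <- !(alignment %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("alignment contains non-ACGT characters (e.g. '",
         alignment[which(bad)[1L]], "')")
  pop_labels <- as.integer(pop_labels)
  if (length(pop_labels) != nrow(alignment) || !all(pop_labels %in% 1:2))
    stop("pop_labels must give a label in {1,2} for every sequence")
  if (!all(pop_labels == sort(pop_labels)))
    stop("sequences must be ordered population 1 first, then population 2")
  if (sum(pop_labels == 1L) < 1L || sum(pop_labels == 2L) < 1L)
    stop("each population needs at least one sequence")
  if (!is.numeric(u) || length(u) != 1L || u <= 0)
    stop("u must be a positive scalar")
  if (!is.null(ancestral_row)) {
    ancestral_row <- as.integer(ancestral_row)
    if (ancestral_row < 1L || ancestral_row > nrow(alignment))
      stop("ancestral_row out of range")
    if (is.null(ancestral)) ancestral <- alignment[ancestral_row, ]
  }
  if (!is.null(ancestral)) {
    ancestral <- toupper(ancestral)
    if (length(ancestral) != ncol(alignment) ||
        !all(ancestral %in% c("A", "C", "G", "T")))
      stop("ancestral must be an ACGT vector with one base per site")
  }
  structure(list(name = as.character(name), alignment = alignment,
                 pop_labels = pop_labels, model = model, u = u,
                 ancestral = ancestral, ancestral_row = ancestral_row),
            class = "im_locus")
}

#' @export
print.im_locus <- function(x, ...) {
  cat(sprintf("<im_locus '%s'> %s, %d + %d sequences, %d sites, u = %g%s\n",
              x$name, x$model, sum(x$pop_labels == 1L),
              sum(x$pop_labels == 2L), ncol(x$alignment), x$u,
              if (!is.null(x$ancestral)) ", polarized" else ""))
  invisible(x)
}

#' Construct a multi-locus dataset
#'
#' @param loci List of [im_locus()] objects with unique names.
#' @param metadata Optional free-text provenance string.
#' @return An object of class `im_dataset`.
#' @export
im_dataset <- function(loci, metadata = "") {
  if (!length(loci)) stop("a dataset needs at least one locus")
  if (inherits(loci, "im_locus")) loci <- list(loci)
  stopifnot(all(vapply(loci, inherits, logical(1), "im_locus")))
  nms <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("locus names must be unique")
  names(loci) <- nms
  structure(list(loci = loci, metadata = as.character(metadata)),
            class = "im_dataset")
}

#' @export
print.im_dataset <- function(x, ...) {
  cat(sprintf("<im_dataset> %d locus/loci\n", length(x$loci)))
  for (l in x$loci) print(l)
  invisible(x)
}

# number of sequences per population for a locus
locus_counts <- function(locus) {
  c(N1 = sum(locus$pop_labels == 1L), N2 = sum(locus$pop_labels == 2L))
}

#' Read a multi-locus dataset
#'
#' Two dialects are supported. The native `im-text` format is a plain-text
#' block format: line 1 holds the number of loci; each locus starts with a
#' header line `name N1 N2 n model u [anc|row]` followed by `N1+N2` lines
#' `label sequence` (population 1 lines first) and, when the header's 7th
#' token is the literal `anc`, one additional `anc sequence` line giving the
#' ancestral base at every site. An integer 7th token designates an alignment
#' row as the ancestral reference instead. Lines starting with `#` and blank
#' lines are ignored. The `fasta+popmap` dialect takes one FASTA file per
#' locus plus a two-column tab-separated map from sequence id to population
#' label.
#'
#' @param path For `im-text`: path of the file. For `fasta+popmap`: character
#'   vector of per-locus FASTA paths.
#' @param format `"im-text"` (default) or `"fasta+popmap"`.
#' @param popmap Path of the population map (required for `fasta+popmap`).
#' @param model,u Model tag and mutation scale applied to FASTA loci.
#' @return An [im_dataset()].
#' @export
read_im_data <- function(path, format = c("im-text", "fasta+popmap"),
                         popmap = NULL, model = "HKY", u = 1) {
  format <- match.arg(format)
  if (format == "im-text") read_im_text(path) else
    read_fasta_popmap(path, popmap, model = model, u = u)
}

read_im_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("empty input file: ", path)
  lns <- raw[keep]
  lineno <- keep # original line numbers for error messages
  i <- 1L
  perr <- function(msg, at = i) stop(sprintf("%s (line %d)", msg, lineno[at]),
                                     call. = FALSE)
  nl <- suppressWarnings(as.integer(trimws(lns[1L])))
  if (is.na(nl) || nl < 1L) perr("first line must be the number of loci", 1L)
  i <- 2L
  loci <- vector("list", nl)
  for (l in seq_len(nl)) {
    if (i > length(lns)) perr("unexpected end of file in locus header",
                              length(lns))
    tk <- strsplit(trimws(lns[i]), "\\s+")[[1L]]
    if (length(tk) < 6L || length(tk) > 7L)
      perr("malformed locus header (need: name N1 N2 n model u [anc|row])")
    name <- tk[1L]
    N1 <- suppressWarnings(as.integer(tk[2L]))
    N2 <- suppressWarnings(as.integer(tk[3L]))
    n <- suppressWarnings(as.integer(tk[4L]))
    mod <- tk[5L]
    uu <- suppressWarnings(as.numeric(tk[6L]))
    if (is.na(N1) || is.na(N2) || is.na(n) || N1 < 1L || N2 < 1L || n < 1L)
      perr("malformed locus header counts")
    if (!mod %in% c("HKY", "IS")) perr(paste0("unknown model tag '", mod, "'"))
    if (is.na(uu) || uu <= 0) perr("mutation scale u must be positive")
    anc_flag <- FALSE; anc_row <- NULL
    if (length(tk) == 7L) {
      if (tk[7L] == "anc") anc_flag <- TRUE
      else {
        anc_row <- suppressWarnings(as.integer(tk[7L]))
        if (is.na(anc_row)) perr("7th header token must be 'anc' or a row index")
      }
    }
    hdr_i <- i
    i <- i + 1L
    N <- N1 + N2
    aln <- matrix("", N, n)
    labs <- integer(N)
    for (r in seq_len(N)) {
      if (i > length(lns)) perr("unexpected end of file in alignment",
                                length(lns))
      tk2 <- strsplit(trimws(lns[i]), "\\s+")[[1L]]
      if (length(tk2) != 2L) perr("expected 'label sequence'")
      lab <- suppressWarnings(as.integer(tk2[1L]))
      if (is.na(lab) || !lab %in% 1:2) perr("population label must be 1 or 2")
      sq <- strsplit(toupper(tk2[2L]), "")[[1L]]
      if (length(sq) != n)
        perr(sprintf("ragged alignment: sequence has %d sites, expected %d",
                     length(sq), n))
      if (!all(sq %in% c("A", "C", "G", "T")))
        perr("non-ACGT character in sequence")
      expected <- if (r <= N1) 1L else 2L
      if (lab != expected)
        perr(sprintf("population %d sequence expected here", expected))
      aln[r, ] <- sq
      labs[r] <- lab
      i <- i + 1L
    }
    anc <- NULL
    if (anc_flag) {
      if (i > length(lns)) perr("missing ancestral line", length(lns))
      tk3 <- strsplit(trimws(lns[i]), "\\s+")[[1L]]
      if (length(tk3) != 2L || tk3[1L] != "anc")
        perr("expected 'anc sequence' line")
      anc <- strsplit(toupper(tk3[2L]), "")[[1L]]
      if (length(anc) != n) perr("ragged ancestral sequence")
      i <- i + 1L
    }
    loci[[l]] <- im_locus(name, aln, labs, mod, uu, ancestral = anc,
                          ancestral_row = anc_row)
    if (FALSE) hdr_i # keep lint quiet
  }
  if (i <= length(lns)) perr("trailing content after last locus")
  im_dataset(loci, metadata = paste("read from", path))
}

read_fasta_popmap <- function(fasta_paths, popmap, model = "HKY", u = 1) {
  if (is.null(popmap) || !file.exists(popmap))
    stop("fasta+popmap format requires an existing popmap file")
  pm <- read.delim(popmap, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(pm) < 2L) stop("popmap must have two tab-separated columns")
  labs <- setNames(as.integer(pm[[2L]]), as.character(pm[[1L]]))
  if (any(is.na(labs)) || !all(labs %in% 1:2))
    stop("popmap labels must be 1 or 2")
  loci <- lapply(fasta_paths, function(fp) {
    if (!file.exists(fp)) stop("file not found: ", fp)
    dna <- ape::read.FASTA(fp)
    chr <- as.character(dna)
    if (length(unique(lengths(chr))) != 1L)
      stop("ragged alignment in ", fp)
    aln <- toupper(do.call(rbind, chr))
    ids <- names(dna)
    if (!all(ids %in% names(labs)))
      stop("sequence id(s) missing from popmap in ", fp)
    pl <- labs[ids]
    o <- order(pl)
    im_locus(sub("\\.[^.]*$", "", basename(fp)), aln[o, , drop = FALSE],
             pl[o], model = model, u = u)
  })
  im_dataset(loci, metadata = paste("read from", length(fasta_paths),
                                    "FASTA file(s) +", popmap))
}

#' Write a dataset in the im-text format
#'
#' @param dataset An [im_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_im_data <- function(dataset, path) {
  stopifnot(inherits(dataset, "im_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(dataset$loci)), con)
  for (loc in dataset$loci) {
    cnt <- locus_counts(loc)
    extra <- if (!is.null(loc$ancestral) && is.null(loc$ancestral_row)) " anc"
             else if (!is.null(loc$ancestral_row))
               paste0(" ", loc$ancestral_row) else ""
    writeLines(sprintf("%s %d %d %d %s %.17g%s", loc$name, cnt[["N1"]],
                       cnt[["N2"]], ncol(loc$alignment), loc$model, loc$u,
                       extra), con)
    for (r in seq_len(nrow(loc$alignment)))
      writeLines(paste(loc$pop_labels[r],
                       paste(loc$alignment[r, ], collapse = "")), con)
    if (!is.null(loc$ancestral) && is.null(loc$ancestral_row))
      writeLines(paste("anc", paste(loc$ancestral, collapse = "")), con)
  }
  invisible(path)
}

# integer codes 1..4 for A,C,G,T
BASES <- c("A", "C", "G", "T")

locus_codes <- function(locus) {
  matrix(match(locus$alignment, BASES), nrow(locus$alignment))
}

# empirical base frequencies with +1 pseudocount per base so all pi > 0
empirical_pi <- function(locus) {
  cnt <- tabulate(locus_codes(locus), 4L) + 1
  cnt / sum(cnt)
}
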