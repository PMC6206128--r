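# File formats: genotype tables (STRUCTURE two-row and GenePop dialects),
# FASTA alignments, site metadata tables, and result serialization.

#' Construct a diploid multi-allelic genotype table
#'
#' The central container for microsatellite data: one row per individual,
#' one column per locus, each cell an *unordered* pair of integer allele
#' labels (repeat lengths) or missing.  Microsatellites are unphased, so
#' no allele order is ever implied; both allele matrices are stored with
#' `a1 <= a2` canonically.
#'
#' @param individuals Character vector of unique sample ids.
#' @param loci Character vector of locus ids.
#' @param a1,a2 Integer matrices (`n x L`) of allele labels; `NA` marks a
#'   missing genotype (always in both matrices simultaneously).
#' @param site Optional character vector mapping each individual to a
#'   site id.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, loci, a1, a2, site = NULL) {
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  a1 <- matrix(as.integer(a1), nrow = length(individuals),
               dimnames = list(individuals, loci))
  a2 <- matrix(as.integer(a2), nrow = length(individuals),
               dimnames = list(individuals, loci))
  if (anyDuplicated(individuals))
    stop_pondmix("duplicate sample id(s): ",
                 paste(unique(individuals[duplicated(individuals)]),
                       collapse = ", "))
  if (!identical(dim(a1), dim(a2)))
    stop_pondmix("allele matrices must have identical dimensions")
  if (any(xor(is.na(a1), is.na(a2))))
    stop_pondmix("half-missing genotypes: both alleles must be missing together")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop_pondmix("allele labels must be positive integers")
  # canonical unordered storage
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  if (is.null(site)) site <- rep(NA_character_, length(individuals))
  site <- as.character(site)
  stopifnot(length(site) == length(individuals))
  names(site) <- individuals
  structure(list(individuals = individuals, loci = loci,
                 a1 = a1, a2 = a2, site = site),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  n_miss <- sum(is.na(x$a1))
  cat(sprintf("genotype_table: %d individuals x %d loci (%d missing genotypes)\n",
              length(x$individuals), length(x$loci), n_miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype table
#' @param gt A `genotype_table`.
#' @return Integer count.
#' @export
n_individuals <- function(gt) length(gt$individuals)

#' @rdname n_individuals
#' @export
n_loci <- function(gt) length(gt$loci)

#' Subset a genotype table by individual
#' @param gt A `genotype_table`.
#' @param keep Logical, integer or character index of individuals.
#' @return A `genotype_table`.
#' @export
subset_individuals <- function(gt, keep) {
  if (is.character(keep)) keep <- match(keep, gt$individuals)
  genotype_table(gt$individuals[keep], gt$loci,
                 gt$a1[keep, , drop = FALSE], gt$a2[keep, , drop = FALSE],
                 gt$site[keep])
}

#' Combine genotype tables sharing a locus list
#' @param ... `genotype_table` objects with identical loci.
#' @return A `genotype_table`.
#' @export
bind_genotypes <- function(...) {
  gts <- list(...)
  loci <- gts[[1]]$loci
  for (g in gts) if (!identical(g$loci, loci))
    stop_pondmix("genotype tables have different locus lists")
  genotype_table(unlist(lapply(gts, `[[`, "individuals")), loci,
                 do.call(rbind, lapply(gts, `[[`, "a1")),
                 do.call(rbind, lapply(gts, `[[`, "a2")),
                 unlist(lapply(gts, `[[`, "site")))
}

#' Read a genotype file
#'
#' Two dialects are supported.  `structure_2row`: a header line of
#' whitespace-separated locus names, then two rows per individual, each
#' `id site allele_1 ... allele_L`; missing alleles are coded `-9` (any
#' negative or zero code is treated as missing).  `genepop`: a title
#' line, one locus name per line (or one comma-separated line), `Pop`
#' separators, then `id , g1 g2 ...` with each genotype the
#' concatenation of two equal-width (2- or 3-digit) allele codes;
#' `00`/`000` codes are missing.  GenePop carries no site names, so
#' sites are labelled `pop1`, `pop2`, ... in file order.
#'
#' @param path File path.
#' @param dialect `"structure_2row"` or `"genepop"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, dialect = c("structure_2row", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_pondmix("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "structure_2row") read_structure_2row(lines, path)
  else read_genepop(lines, path)
}

read_structure_2row <- function(lines, path) {
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  if (length(body) %% 2 != 0)
    stop_pondmix("structure_2row file has an odd number of genotype rows")
  parse_row <- function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) != length(loci) + 2)
      stop_pondmix(sprintf(
        "parse error at line %d of %s: expected %d fields, found %d",
        i + 1, path, length(loci) + 2, length(f)))
    f
  }
  n <- length(body) / 2
  ids <- character(n); sites <- character(n)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) {
    r1 <- parse_row(2 * i - 1); r2 <- parse_row(2 * i)
    if (r1[1] != r2[1])
      stop_pondmix(sprintf("row pair mismatch near line %d: '%s' vs '%s'",
                           2 * i, r1[1], r2[1]))
    ids[i] <- r1[1]; sites[i] <- r1[2]
    v1 <- suppressWarnings(as.integer(r1[-(1:2)]))
    v2 <- suppressWarnings(as.integer(r2[-(1:2)]))
    v1[is.na(v1) | v1 <= 0] <- NA_integer_
    v2[is.na(v2) | v2 <= 0] <- NA_integer_
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
    a1[i, ] <- v1; a2[i, ] <- v2
  }
  genotype_table(ids, loci, a1, a2, sites)
}

read_genepop <- function(lines, path) {
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop_pondmix("genepop file lacks a 'Pop' line after the locus names")
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); sites <- character()
  rows1 <- list(); rows2 <- list()
  pop_i <- 0
  for (ln in lines[first_pop:length(lines)]) {
    if (toupper(trimws(ln)) == "POP") { pop_i <- pop_i + 1; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) != 2)
      stop_pondmix("malformed genepop row (missing comma): ", ln)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop_pondmix(sprintf(
        "genepop row for '%s': expected %d genotypes, found %d",
        id, length(loci), length(codes)))
    w <- nchar(codes)
    if (any(w %% 2 != 0))
      stop_pondmix("genepop genotype with odd digit count in row for ", id)
    half <- w / 2
    v1 <- as.integer(substr(codes, 1, half))
    v2 <- as.integer(substr(codes, half + 1, w))
    v1[v1 == 0] <- NA_integer_; v2[v2 == 0] <- NA_integer_
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
    ids <- c(ids, id); sites <- c(sites, paste0("pop", pop_i))
    rows1[[length(rows1) + 1]] <- v1
    rows2[[length(rows2) + 1]] <- v2
  }
  genotype_table(ids, loci, do.call(rbind, rows1), do.call(rbind, rows2),
                 sites)
}

#' Write a genotype table
#'
#' @param gt A [genotype_table()].
#' @param path Output file path.
#' @param dialect `"structure_2row"` or `"genepop"` (3-digit allele
#'   codes; labels above 999 are rejected for this dialect).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path,
                            dialect = c("structure_2row", "genepop")) {
  dialect <- match.arg(dialect)
  if (dialect == "structure_2row") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(gt$loci, collapse = " "), con)
    for (i in seq_along(gt$individuals)) {
      s <- gt$site[i]; if (is.na(s)) s <- "NA"
      r1 <- gt$a1[i, ]; r2 <- gt$a2[i, ]
      r1[is.na(r1)] <- -9L; r2[is.na(r2)] <- -9L
      writeLines(paste(c(gt$individuals[i], s, r1), collapse = " "), con)
      writeLines(paste(c(gt$individuals[i], s, r2), collapse = " "), con)
    }
  } else {
    if (any(gt$a2 > 999, na.rm = TRUE))
      stop_pondmix("genepop dialect limits allele labels to 999")
    con <- file(path, "w"); on.exit(close(con))
    writeLines("pondmix genepop export", con)
    writeLines(gt$loci, con)
    site <- gt$site
    site[is.na(site)] <- "NA"
    for (s in unique(site)) {
      writeLines("Pop", con)
      for (i in which(site == s)) {
        g1 <- gt$a1[i, ]; g2 <- gt$a2[i, ]
        g1[is.na(g1)] <- 0L; g2[is.na(g2)] <- 0L
        writeLines(paste0(gt$individuals[i], " , ",
                          paste(sprintf("%03d%03d", g1, g2),
                                collapse = " ")), con)
      }
    }
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' All records must share one length; lowercase is normalised to
#' uppercase.  Only `A`, `C`, `G`, `T`, `N` and `-` are permitted.
#'
#' @param path FASTA file path.
#' @return A `sequence_alignment`: a named character vector of
#'   equal-length uppercase sequences with attribute `length`.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  sequence_alignment(seqs)
}

#' Construct a sequence alignment from named sequences
#' @param seqs Named character vector of equal-length sequences.
#' @return A `sequence_alignment`.
#' @export
sequence_alignment <- function(seqs) {
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    bad <- names(seqs)[lens != lens[1]]
    stop_pondmix("ragged alignment; offending records: ",
                 paste(bad, collapse = ", "))
  }
  if (any(grepl("[^ACGTN-]", seqs)))
    stop_pondmix("alignment contains characters outside {A,C,G,T,N,-}")
  structure(seqs, length = unname(lens[1]), class = "sequence_alignment")
}

#' @export
print.sequence_alignment <- function(x, ...) {
  cat(sprintf("sequence_alignment: %d sequences of length %d bp\n",
              length(x), attr(x, "length")))
  invisible(x)
}

#' Write an alignment as FASTA
#' @param aln A `sequence_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(aln)) {
    writeLines(paste0(">", names(aln)[i]), con)
    writeLines(unclass(aln)[i], con)
  }
  invisible(path)
}

# alignment as a character matrix (rows = samples, cols = positions)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Read a site metadata table
#'
#' A TSV/CSV with required columns `site`, `lat`, `lon` and optional
#' `group`, `taxon`, `transects`.  `transects` lists memberships as
#' semicolon-separated `name:rank` entries (e.g. `"atl:1;ebro:4"`);
#' rank order must be unique within a transect.
#'
#' @param path File path (delimiter inferred from the extension:
#'   `.csv` comma, otherwise tab).
#' @return A `data.frame` of class `site_table` with an attribute
#'   `transects`: a long `data.frame` (site, transect, rank).
#' @export
read_sites <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE, check.names = FALSE)
  site_table(df)
}

#' Construct/validate a site table
#' @param df `data.frame` with columns `site`, `lat`, `lon` and optional
#'   `group`, `taxon`, `transects`.
#' @return A validated `site_table`.
#' @export
site_table <- function(df) {
  need <- c("site", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_pondmix("site table lacks required column(s): ",
                 paste(miss, collapse = ", "))
  df$site <- as.character(df$site)
  df$lat <- as.numeric(df$lat); df$lon <- as.numeric(df$lon)
  if (any(abs(df$lat) > 90, na.rm = TRUE))
    stop_pondmix("latitude outside [-90, 90]")
  if (any(abs(df$lon) > 180, na.rm = TRUE))
    stop_pondmix("longitude outside [-180, 180]")
  if (anyDuplicated(df$site))
    stop_pondmix("duplicate site id(s) in site table")
  tr <- data.frame(site = character(), transect = character(),
                   rank = integer(), stringsAsFactors = FALSE)
  if ("transects" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      spec <- df$transects[i]
      if (is.na(spec) || !nzchar(spec)) next
      for (ent in strsplit(spec, ";")[[1]]) {
        kv <- strsplit(trimws(ent), ":")[[1]]
        if (length(kv) != 2)
          stop_pondmix("malformed transect entry '", ent, "' for site ",
                       df$site[i])
        tr <- rbind(tr, data.frame(site = df$site[i], transect = kv[1],
                                   rank = as.integer(kv[2]),
                                   stringsAsFactors = FALSE))
      }
    }
    for (t in unique(tr$transect)) {
      rk <- tr$rank[tr$transect == t]
      if (anyDuplicated(rk))
        stop_pondmix("duplicate rank in transect '", t, "'")
    }
  }
  attr(df, "transects") <- tr
  class(df) <- c("site_table", "data.frame")
  df
}

#' Write a site table
#' @param sites A `site_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Serialize a result object
#'
#' Data frames become TSV; everything else becomes pretty-printed JSON.
#'
#' @param obj A `data.frame` or serializable list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  if (is.data.frame(obj)) {
    write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}
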