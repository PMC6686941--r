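#' Write genotypes to a file
#'
#' `format = "matrix"` writes a delimited dosage table (loci in rows by
#' default, with locus names; `orientation = "individuals"` transposes).
#' `format = "vcf"` writes VCFv4.2 with one record per locus and phased GT
#' fields `x|y` mapping the alpha and beta strand bits to allele indices
#' (bit 1 -> allele 1). VCF POS must be a positive integer while map
#' coordinates are Morgans, so POS is the locus rank within its chromosome
#' and the genetic position is carried as centimorgans in the INFO `cM` tag.
#'
#' @param population a `population`.
#' @param path output path.
#' @param format `"matrix"` or `"vcf"`.
#' @param orientation for matrix output: `"loci"` (rows, default) or
#'   `"individuals"`.
#' @param header named character vector added to the reproducibility header.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(population, path,
                            format = c("matrix", "vcf"),
                            orientation = c("loci", "individuals"),
                            header = character()) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!inherits(population, "population")) stop_input("not a population")
  if (format == "matrix") {
    M <- genotype_numeric(population)
    if (orientation == "individuals") M <- t(M)
    df <- data.frame(id = rownames(M), M, check.names = FALSE)
    write_with_header(df, path, c(header, orientation = orientation))
  } else {
    write_vcf(population, path, header)
  }
  invisible(path)
}

write_vcf <- function(population, path, header = character()) {
  spp <- population$specie
  map <- spp$map
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_io(paste0("cannot open for writing: ", path)))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=bitqg ", as.character(packageVersion("bitqg"))),
    if (length(header)) paste0("##", names(header), "=", unname(header)),
    "##INFO=<ID=cM,Number=1,Type=Float,Description=\"Genetic map position in centimorgans\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype, alpha strand first\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", population$labels), collapse = "\t")), con)
  # allele bit -> VCF allele index, per strand
  gt_alpha <- gt_beta <- matrix(0L, nrow(map), length(population))
  row0 <- 0L
  for (ch in spp$chr_names) {
    n <- spp$n_loci[[ch]]
    for (j in seq_along(population$individuals)) {
      pair <- population$individuals[[j]]$genome[[ch]]
      gt_alpha[row0 + seq_len(n), j] <- as.integer(as.logical(pair$alpha))
      gt_beta[row0 + seq_len(n), j] <- as.integer(as.logical(pair$beta))
    }
    row0 <- row0 + n
  }
  pos_rank <- unlist(lapply(split(seq_len(nrow(map)),
                                  factor(map$chr, levels = spp$chr_names)),
                            seq_along), use.names = FALSE)
  gt <- matrix(paste0(gt_alpha, "|", gt_beta), nrow = nrow(map))
  lines <- paste(map$chr, pos_rank, map$snp, "A", "T", ".", "PASS",
                 sprintf("cM=%g", map$pos * 100), "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
}

#' Read a genotype matrix file
#'
#' Reads the `"matrix"` dialect written by [write_genotypes()] back into a
#' dosage matrix (loci in rows regardless of the stored orientation).
#'
#' @param path file path.
#' @return integer dosage matrix, loci in rows.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path))
  hdr <- read_header(path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "integer"
  if (identical(hdr[["orientation"]], "individuals")) M <- t(M)
  M
}

read_header <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "## ")]
  kv <- sub("^## ", "", lines)
  eq <- regexpr("=", kv, fixed = TRUE)
  setNames(substring(kv, eq + 1L), substring(kv, 1L, eq - 1L))
}

#' Write gametes to a file
#'
#' One row per gamete: tab-separated bit strings, one column per chromosome,
#' leftmost character = first (smallest-position) locus.
#'
#' @param gams list of gametes from [gametes()].
#' @param path output path.
#' @param header named character vector for the reproducibility header.
#' @return `path`, invisibly.
#' @export
write_gametes <- function(gams, path, header = character()) {
  if (!length(gams)) stop_input("no gametes")
  df <- as.data.frame(lapply(names(gams[[1]]), function(ch)
    vapply(gams, function(g) strand_to_string(g[[ch]]), character(1))))
  names(df) <- paste0("chr", names(gams[[1]]))
  df <- cbind(gamete = seq_along(gams), df)
  write_with_header(df, path, header)
  invisible(path)
}

#' Dump and restore genome state
#'
#' Plain-text state dump: one row per (individual, chromosome) with both
#' strands as bit strings whose leftmost character is the first locus.
#' `read_genomes()` reconstructs the individuals in a given specie (the map
#' must match the dump).
#'
#' @param pop a `population`.
#' @param path file path.
#' @param specie the specie the restored individuals belong to.
#' @param header named character vector for the reproducibility header.
#' @return `write_genomes`: `path` invisibly; `read_genomes`: a `population`.
#' @export
write_genomes <- function(pop, path, header = character()) {
  if (!inherits(pop, "population")) stop_input("not a population")
  rows <- purrr::map(seq_along(pop$individuals), function(i) {
    ind <- pop$individuals[[i]]
    tibble::tibble(
      id = pop$labels[i],
      chr = names(ind$genome),
      alpha = vapply(ind$genome, function(p) strand_to_string(p$alpha),
                     character(1)),
      beta = vapply(ind$genome, function(p) strand_to_string(p$beta),
                    character(1)))
  })
  write_with_header(as.data.frame(dplyr::bind_rows(rows)), path, header)
  invisible(path)
}

#' @rdname write_genomes
#' @export
read_genomes <- function(path, specie) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path))
  if (!is_specie(specie)) stop_input("not a specie")
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  ids <- unique(df$id)
  inds <- lapply(ids, function(one) {
    rows <- df[df$id == one, ]
    if (!setequal(rows$chr, specie$chr_names))
      stop_input("dump chromosomes do not match the specie map")
    genome <- lapply(setNames(specie$chr_names, specie$chr_names), function(ch) {
      r <- rows[rows$chr == ch, ]
      a <- strand_from_string(r$alpha)
      b <- strand_from_string(r$beta)
      if (a$n != specie$n_loci[[ch]] || b$n != specie$n_loci[[ch]])
        stop_input("dump strand length does not match the specie map")
      list(alpha = a, beta = b)
    })
    new_individual(specie, genome)
  })
  population(inds, labels = ids)
}

#' Read a key = value configuration file
#'
#' Mirrors the command-line flags: one `key = value` per line, `#` comments
#' allowed. Values are returned as character.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop_input("config lines must be key = value")
  vals <- as.list(trimws(substring(lines, eq + 1L)))
  setNames(vals, trimws(substring(lines, 1L, eq - 1L)))
}
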