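# On-disk conventions: internal coordinates are 1-based closed; BED output
# is 0-based half-open (converted on write/read); VCF/GFF3 are 1-based.

vcf_ref <- "A"
vcf_alt_founder <- "G"
vcf_alt_third <- "T"

#' Write genotype calls to VCF v4.2
#'
#' The reference allele encodes the B73 allele, the first alternate the
#' Mo17 allele and a second alternate any third-origin allele; calls carry
#' `GT` and `GQ` FORMAT fields.
#'
#' @param calls Genotype-call tibble (`sample`, `chrom`, `pos`, `call`,
#'   `other_hom`, `gq`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(calls, path) {
  samples <- sort(unique(calls$sample))
  gt_of <- function(call, other_hom) {
    dplyr::case_when(
      call == "HOM_REF" ~ "0/0",
      call == "HOM_ALT" ~ "1/1",
      call == "HET" ~ "0/1",
      call == "OTHER" & !is.na(other_hom) & other_hom ~ "2/2",
      call == "OTHER" ~ "0/2",
      TRUE ~ "./."
    )
  }
  wide <- calls |>
    mutate(field = paste0(gt_of(.data$call, .data$other_hom), ":", .data$gq)) |>
    select("chrom", "pos", "sample", "field") |>
    pivot_wider(names_from = "sample", values_from = "field",
                values_fill = "./.:0") |>
    arrange(.data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=speqtl",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  pos_str <- sprintf("%d", as.integer(wide$pos))
  fields <- apply(as.matrix(wide[, samples, drop = FALSE]), 1, paste,
                  collapse = "\t")
  body <- paste(wide$chrom, pos_str, paste0(wide$chrom, "_", pos_str),
                vcf_ref, paste(vcf_alt_founder, vcf_alt_third, sep = ","),
                ".", "PASS", ".", "GT:GQ", fields, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype calls from a VCF written by [write_genotype_vcf()]
#'
#' @param path VCF file.
#' @return Genotype-call tibble (`sample`, `chrom`, `pos`, `call`,
#'   `other_hom`, `gq`).
#' @export
read_genotype_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (length(body) == 0 || !startsWith(body[1], "#CHROM")) {
    abort(paste0("not a VCF: missing #CHROM header line in ", path))
  }
  hdr <- strsplit(body[1], "\t")[[1]]
  if (length(hdr) < 10) abort("VCF has no sample columns")
  samples <- hdr[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  short <- which(lengths(rows) != length(hdr))
  if (length(short) > 0) {
    abort(sprintf("malformed VCF record at %s line %d", path, short[1] + 1L))
  }
  purrr::map_dfr(rows, function(r) {
    fields <- r[-(1:9)]
    parts <- strsplit(fields, ":")
    gt <- vapply(parts, `[`, "", 1)
    gq <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    call <- dplyr::case_when(
      gt == "0/0" ~ "HOM_REF", gt == "1/1" ~ "HOM_ALT", gt == "0/1" ~ "HET",
      gt %in% c("2/2", "0/2", "1/2") ~ "OTHER", TRUE ~ "MISSING"
    )
    tibble(sample = samples, chrom = r[1], pos = as.numeric(r[2]),
           call = call,
           other_hom = if_else(call == "OTHER", gt == "2/2", NA),
           gq = dplyr::coalesce(gq, 0L))
  })
}

#' Write classified regions as a BED6 table
#'
#' Internal 1-based closed intervals are converted to BED's 0-based
#' half-open convention; the name column carries `<sample>|<origin>`.
#'
#' @param regions Region tibble (`sample`, `chrom`, `start`, `end`,
#'   `origin`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t+",
                   regions$chrom, as.integer(regions$start) - 1L,
                   as.integer(regions$end), regions$sample, regions$origin)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 region table written by [write_regions_bed()]
#'
#' @param path BED file.
#' @return Region tibble with 1-based closed coordinates.
#' @export
read_regions_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start0", "end", "name",
                                            "score", "strand"),
                        col_types = "cddcdc", progress = FALSE)
  df |>
    tidyr::separate_wider_delim("name", "|", names = c("sample", "origin")) |>
    mutate(start = .data$start0 + 1) |>
    select("sample", "chrom", "start", "end", "origin")
}

#' Write gene models as GFF3
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `gc`,
#'   `length`, `syntenic`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  lines <- sprintf(
    "%s\tspeqtl\tgene\t%d\t%d\t.\t+\t.\tID=%s;gc=%.4f;gene_length=%d;syntenic=%s",
    genes$chrom, as.integer(genes$start), as.integer(genes$end),
    genes$gene_id, genes$gc, as.integer(genes$length),
    if_else(genes$syntenic, "1", "0")
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read gene models from a GFF3 written by [write_genes_gff3()]
#'
#' @param path GFF3 file.
#' @return Gene tibble.
#' @export
read_genes_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t")
  attr_get <- function(a, key) {
    sub(paste0(".*", key, "="), "", regmatches(a, regexpr(paste0(key, "=[^;]+"), a)))
  }
  purrr::map_dfr(f, function(r) {
    tibble(gene_id = attr_get(r[9], "ID"), chrom = r[1],
           start = as.numeric(r[4]), end = as.numeric(r[5]),
           gc = as.numeric(attr_get(r[9], "gc")),
           length = as.numeric(attr_get(r[9], "gene_length")),
           syntenic = attr_get(r[9], "syntenic") == "1")
  })
}
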