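#' @importFrom stats cor cor.test lm.fit p.adjust pt phyper qnorm rbinom rnorm
#' @importFrom stats complete.cases kmeans ks.test median optimize prcomp
#' @importFrom stats quantile rlnorm runif sd setNames smooth.spline var
#' @importFrom stats wilcox.test predict resid
#' @importFrom utils head modifyList
NULL

# ---- marker IDs -------------------------------------------------------------

#' Parse marker identifiers of the form "chrXIV:466588_T/G"
#'
#' Marker IDs encode the chromosome, the 1-based base-pair position, and the
#' two parental alleles (BY allele first, RM allele second), e.g.
#' `"chrXIV:466588_T/G"`.
#'
#' @param id Character vector of marker IDs.
#' @return A data.frame with columns `id`, `chrom`, `pos` (integer),
#'   `allele_by`, `allele_rm`.
#' @examples
#' parse_marker_id("chrXIV:466588_T/G")
#' @export
parse_marker_id <- function(id) {
  stopifnot(is.character(id), length(id) >= 1L)
  pat <- "^([A-Za-z0-9_.]+):([0-9]+)_([A-Za-z]+)/([A-Za-z]+)$"
  ok <- grepl(pat, id)
  if (!all(ok)) {
    stop("malformed marker ID(s): ", paste(utils::head(id[!ok], 5L), collapse = ", "))
  }
  pos <- as.integer(sub(pat, "\\2", id))
  if (any(pos < 1L)) stop("marker position must be >= 1")
  data.frame(
    id = id,
    chrom = sub(pat, "\\1", id),
    pos = pos,
    allele_by = sub(pat, "\\3", id),
    allele_rm = sub(pat, "\\4", id),
    stringsAsFactors = FALSE
  )
}

#' Format markers back into ID strings
#'
#' Inverse of [parse_marker_id()]: `format_marker_id(parse_marker_id(x)) == x`.
#'
#' @param markers A data.frame with columns `chrom`, `pos`, `allele_by`,
#'   `allele_rm`.
#' @return Character vector of marker IDs.
#' @export
format_marker_id <- function(markers) {
  paste0(markers$chrom, ":", markers$pos, "_", markers$allele_by, "/", markers$allele_rm)
}

# ---- genome layout ----------------------------------------------------------

#' Define a genome layout (chromosome names and lengths)
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp.
#' @return A data.frame of class `genome_layout`.
#' @export
genome_layout <- function(chrom, length) {
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length < 1)) stop("chromosome lengths must be positive")
  out <- data.frame(chrom = as.character(chrom), length = as.numeric(length),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

.chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

# ---- genotype matrix --------------------------------------------------------

#' Construct a genotype matrix for a segregant panel
#'
#' Genotypes are coded BY = -1, RM = +1 so that a positive trait-genotype
#' correlation means the RM allele increases the trait. Genotypes must be
#' complete (no missing values); markers are stored genome-ordered.
#'
#' @param values Numeric matrix, segregants x markers, entries in \{-1, +1\},
#'   with rownames (segregant IDs) and colnames (marker IDs).
#' @param markers Marker table as returned by [parse_marker_id()]; parsed from
#'   `colnames(values)` when omitted.
#' @param layout A [genome_layout()]; inferred from marker extents if omitted.
#' @return An object of class `genotype_matrix` with elements `geno`,
#'   `markers`, `layout`.
#' @export
genotype_matrix <- function(values, markers = NULL, layout = NULL) {
  if (is.null(rownames(values))) stop("genotype matrix needs segregant rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate segregant IDs")
  if (anyNA(values)) stop("genotypes must be complete (no missing values)")
  if (!all(values %in% c(-1, 1))) stop("genotype values must be -1 (BY) or +1 (RM)")
  if (is.null(markers)) markers <- parse_marker_id(colnames(values))
  if (ncol(values) != nrow(markers)) stop("marker list does not match column count")
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  values <- values[, ord, drop = FALSE]
  rownames(markers) <- NULL
  if (is.null(layout)) {
    agg <- tapply(markers$pos, markers$chrom, max)
    layout <- genome_layout(names(agg), as.numeric(agg))
  }
  bad <- markers$pos > .chrom_length(layout, markers$chrom)
  if (any(bad)) stop("marker position beyond chromosome end: ", markers$id[which(bad)[1L]])
  structure(list(geno = values, markers = markers, layout = layout),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d segregants x %d markers on %d chromosomes\n",
              nrow(x$geno), ncol(x$geno), nrow(x$layout)))
  invisible(x)
}

# Accept either a genotype_matrix or a bare matrix of +/-1 values.
.geno_values <- function(g) {
  if (inherits(g, "genotype_matrix")) g$geno else as.matrix(g)
}

# ---- trait matrix -----------------------------------------------------------

#' Construct a trait matrix (expression or growth)
#'
#' @param values Numeric matrix, segregants x phenotypes, NA allowed;
#'   rownames are segregant IDs, colnames phenotype IDs.
#' @param kind `"expression"` or `"growth"`.
#' @return The matrix with class `trait_matrix` and a `kind` attribute.
#' @export
trait_matrix <- function(values, kind = c("expression", "growth")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("trait matrix needs segregant rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate segregant IDs")
  if (is.null(colnames(values))) stop("trait matrix needs phenotype colnames")
  structure(values, kind = kind, class = c("trait_matrix", class(values)))
}

.trait_values <- function(x) {
  y <- unclass(x)
  attr(y, "kind") <- NULL
  as.matrix(y)
}

# ---- intervals --------------------------------------------------------------

# 1-based inclusive interval overlap: [a,b] meets [c,d] iff a <= d and c <= b.
.int_overlaps <- function(lo1, hi1, lo2, hi2) lo1 <= hi2 & lo2 <= hi1

# ---- local/trans classification ---------------------------------------------

#' Classify eQTLs as local or trans
#'
#' An eQTL is local when its confidence interval overlaps the gene body
#' extended by 1,000 bp upstream of the 5' end and 200 bp downstream of the
#' 3' end (strand-aware, clipped at chromosome ends); otherwise it is trans.
#' eQTLs on a different chromosome than their gene are always trans.
#'
#' @param qtl QTL table (data.frame with `trait`, `chrom`, `ci_lo`, `ci_hi`).
#' @param genes Gene annotation (data.frame with `gene`, `chrom`, `cds_start`,
#'   `cds_end`, `strand`).
#' @param layout A [genome_layout()].
#' @param upstream,downstream Window extensions in bp.
#' @return Character vector (`"local"`/`"trans"`), one entry per QTL row.
#' @export
classify_eqtl <- function(qtl, genes, layout, upstream = 1000, downstream = 200) {
  i <- match(qtl$trait, genes$gene)
  if (anyNA(i)) stop("QTL trait(s) missing from gene annotation: ",
                     paste(unique(qtl$trait[is.na(i)]), collapse = ", "))
  g <- genes[i, , drop = FALSE]
  if (any(g$cds_start > g$cds_end)) stop("gene annotation with cds_start > cds_end")
  unknown <- !(qtl$chrom %in% layout$chrom)
  if (any(unknown)) stop("unknown chromosome(s): ",
                         paste(unique(qtl$chrom[unknown]), collapse = ", "))
  plus <- g$strand != "-"
  win_lo <- ifelse(plus, g$cds_start - upstream, g$cds_start - downstream)
  win_hi <- ifelse(plus, g$cds_end + downstream, g$cds_end + upstream)
  win_lo <- pmax(win_lo, 1)
  win_hi <- pmin(win_hi, .chrom_length(layout, g$chrom))
  same <- qtl$chrom == g$chrom
  local <- same & .int_overlaps(qtl$ci_lo, qtl$ci_hi, win_lo, win_hi)
  ifelse(local, "local", "trans")
}

# ---- readers / writers ------------------------------------------------------

.read_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE, fill = FALSE)
  dt
}

.check_row_ids <- function(ids, path) {
  if (anyDuplicated(ids)) {
    stop("duplicate row ID '", ids[duplicated(ids)][1L], "' in ", path)
  }
  as.character(ids)
}

#' Read a trait matrix from tab-delimited text
#'
#' Expects a header row, segregant IDs in the first column, `NA` for missing.
#'
#' @param path File path.
#' @param kind `"expression"` or `"growth"`.
#' @return A [trait_matrix()].
#' @export
read_trait_matrix <- function(path, kind = c("expression", "growth")) {
  kind <- match.arg(kind)
  dt <- .read_tsv(path)
  ids <- .check_row_ids(dt[[1L]], path)
  vals <- dt[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1L))
  if (any(bad)) {
    stop("non-numeric values in ", path, ", column '", names(vals)[bad][1L], "'")
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  trait_matrix(m, kind)
}

#' Write a trait matrix as tab-delimited text
#' @param x A [trait_matrix()] or numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_trait_matrix <- function(x, path) {
  m <- if (inherits(x, "trait_matrix")) .trait_values(x) else as.matrix(x)
  df <- data.frame(segregant = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix from tab-delimited text
#'
#' Column names must be parseable marker IDs (see [parse_marker_id()]).
#' Encodings other than \{-1, +1\} are recoded through `recode`, a named
#' vector mapping stored values to -1/+1, e.g. `c("0" = -1, "1" = 1)`.
#'
#' @param path File path.
#' @param recode Optional named numeric vector mapping stored codes to -1/+1.
#' @param layout Optional [genome_layout()].
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, recode = NULL, layout = NULL) {
  dt <- .read_tsv(path)
  ids <- .check_row_ids(dt[[1L]], path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.null(recode)) {
    key <- as.character(m)
    if (!all(key %in% names(recode))) {
      stop("genotype code(s) not covered by recode mapping in ", path)
    }
    m <- matrix(unname(recode[key]), nrow = nrow(m), dimnames = dimnames(m))
  } else {
    storage.mode(m) <- "numeric"
  }
  rownames(m) <- ids
  genotype_matrix(m, layout = layout)
}

#' Write a genotype matrix as tab-delimited text
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotype_matrix <- function(g, path) {
  df <- data.frame(segregant = rownames(g$geno), g$geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

.qtl_cols <- c("trait", "chrom", "peak_pos", "ci_lo", "ci_hi", "lod")

#' Read a QTL table
#'
#' Tab-delimited with columns `trait`, `chrom`, `peak_pos`, `ci_lo`, `ci_hi`,
#' `lod` and optionally `effect_r` (mirroring the deposited column layout).
#'
#' @param path File path.
#' @return A data.frame of QTL records.
#' @export
read_qtl_table <- function(path) {
  dt <- .read_tsv(path)
  missing <- setdiff(.qtl_cols, names(dt))
  if (length(missing)) stop("QTL table ", path, " lacks column(s): ",
                            paste(missing, collapse = ", "))
  validate_qtl_table(dt)
  dt
}

#' Validate QTL record invariants
#' @param qtl A QTL data.frame.
#' @return The table, invisibly; errors on violated invariants.
#' @export
validate_qtl_table <- function(qtl) {
  if (any(qtl$ci_lo > qtl$peak_pos | qtl$peak_pos > qtl$ci_hi)) {
    stop("QTL with peak outside its confidence interval")
  }
  if (any(qtl$lod < 0)) stop("negative LOD score")
  invisible(qtl)
}

#' Write a QTL table
#' @param qtl QTL data.frame.
#' @param path Output path.
#' @export
write_qtl_table <- function(qtl, path) {
  data.table::fwrite(qtl, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-delimited with columns `gene`, `chrom`, `cds_start`, `cds_end`,
#' `strand`.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_gene_annotation <- function(path) {
  dt <- .read_tsv(path)
  need <- c("gene", "chrom", "cds_start", "cds_end", "strand")
  missing <- setdiff(need, names(dt))
  if (length(missing)) stop("gene annotation lacks column(s): ",
                            paste(missing, collapse = ", "))
  if (any(dt$cds_start > dt$cds_end)) stop("gene with cds_start > cds_end")
  dt
}

#' Read a hotspot table
#'
#' Tab-delimited with columns `hotspot`, `chrom`, `ci_lo`, `ci_hi`,
#' `peak_marker`, `n_target_genes`.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_hotspots <- function(path) {
  dt <- .read_tsv(path)
  need <- c("hotspot", "chrom", "ci_lo", "ci_hi", "peak_marker", "n_target_genes")
  missing <- setdiff(need, names(dt))
  if (length(missing)) stop("hotspot table lacks column(s): ",
                            paste(missing, collapse = ", "))
  pk <- parse_marker_id(dt$peak_marker)
  inside <- pk$chrom == dt$chrom & pk$pos >= dt$ci_lo & pk$pos <= dt$ci_hi
  if (!all(inside)) stop("hotspot peak marker outside its interval: ",
                         dt$hotspot[!inside][1L])
  if (any(dt$n_target_genes < 0)) stop("negative target-gene count")
  dt
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("GMT line without genes: line ", which(bad)[1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  sets
}

# Map QTL peaks (chrom, peak_pos) to marker IDs of a genotype matrix.
# Exact position match required; synthetic tables and the deposited tables
# both use genotyped markers as peaks.
.peak_marker_ids <- function(qtl, genotypes) {
  mk <- genotypes$markers
  key <- paste(mk$chrom, mk$pos)
  i <- match(paste(qtl$chrom, qtl$peak_pos), key)
  if (anyNA(i)) {
    stop("QTL peak(s) not present in the genotype map, first: ",
         qtl$chrom[is.na(i)][1L], ":", qtl$peak_pos[is.na(i)][1L])
  }
  mk$id[i]
}
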