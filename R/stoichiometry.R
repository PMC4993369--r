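#' Validate and normalize a peptide-form table
#'
#' Input rows carry the relative abundance of each modification form of a
#' histone peptide site (e.g. H3K4 me0/me1/me2/me3) per strain.  Abundances
#' are renormalized to sum exactly to 1 within each site and strain; both
#' fraction-scale (sum 1) and percent-scale (sum 100) inputs are accepted,
#' any other sum deviating by more than 1% raises a warning (it usually
#' indicates a missing form), and negative abundances are an error.
#'
#' @param table data.frame with columns `site`, `form`, `strain`,
#'   `abundance`.
#' @return the table with `abundance` replaced by unit-sum `fraction`.
#' @export
form_fractions <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("site", "form", "strain", "abundance") %in% names(table)))
  if (any(table$abundance < 0)) stop("negative abundance in peptide-form table")
  if (anyNA(table$abundance)) stop("missing abundance in peptide-form table")
  key <- interaction(table$site, table$strain, drop = TRUE)
  out <- table
  out$fraction <- NA_real_
  for (k in levels(key)) {
    idx <- key == k
    s <- sum(table$abundance[idx])
    if (s <= 0) stop("all-zero abundances for ", k)
    if (abs(s - 1) > 0.01 && abs(s - 100) > 1)
      warning("abundances for ", k, " sum to ", format(s),
              "; renormalizing to 1")
    out$fraction[idx] <- table$abundance[idx] / s
  }
  if (anyDuplicated(paste(table$site, table$strain, table$form)))
    stop("duplicate site/strain/form rows")
  out$abundance <- NULL
  out
}

# fetch the fractions of one site x strain as a named vector
site_fractions <- function(fractions, site, strain) {
  idx <- fractions$site == site & fractions$strain == strain
  if (!any(idx)) stop("no rows for site '", site, "', strain '", strain, "'")
  stats::setNames(fractions$fraction[idx], fractions$form[idx])
}

#' Total methylation at a site
#'
#' The percentage of peptides carrying at least one methyl group: the sum
#' of the me1, me2 and me3 form fractions, as percent.  Together with me0
#' it is exactly 100% for a pure methylation site.
#'
#' @param fractions normalized table from [form_fractions()].
#' @param site site id (e.g. `"H3K4"`).
#' @param strain strain id.
#' @return total methylated fraction, percent.
#' @export
aggregate_methylation <- function(fractions, site, strain = "WT") {
  fr <- site_fractions(fractions, site, strain)
  100 * sum(fr[names(fr) %in% c("me1", "me2", "me3")])
}

#' Compare one modification form between two strains
#'
#' @param fractions normalized table from [form_fractions()].
#' @param site site id.
#' @param form form id.
#' @param strain_a,strain_b the two strains; the change is a minus b
#'   (conventionally mutant minus wild type).
#' @return list with `absolute_pp` (percentage-point change) and
#'   `relative_pct` (percent change relative to strain b).
#' @export
compare_strains <- function(fractions, site, form, strain_a = "mutant",
                            strain_b = "WT") {
  fa <- site_fractions(fractions, site, strain_a)
  fb <- site_fractions(fractions, site, strain_b)
  if (!form %in% names(fa) || !form %in% names(fb))
    stop("form '", form, "' absent at site '", site, "'")
  a <- unname(fa[form]); b <- unname(fb[form])
  list(absolute_pp = 100 * (a - b),
       relative_pct = if (b > 0) 100 * (a - b) / b else Inf)
}

#' Full stoichiometry summary over a peptide-form table
#'
#' Per site and strain: each form's fraction (percent), the total
#' methylated fraction and the unmodified fraction; per site and form: the
#' absolute (percentage-point) and relative (%) change between the two
#' strains.
#'
#' @param table raw peptide-form table (site, form, strain, abundance).
#' @param strain_a,strain_b strains compared (a minus b).
#' @return list with `fractions` (site, strain, form, pct),
#'   `aggregates` (site, strain, total_methylated_pct, unmodified_pct) and
#'   `comparison` (site, form, pct_a, pct_b, absolute_pp, relative_pct).
#' @export
stoichiometry_summary <- function(table, strain_a = "mutant", strain_b = "WT") {
  fr <- form_fractions(table)
  fractions <- data.frame(site = fr$site, strain = fr$strain, form = fr$form,
                          pct = 100 * fr$fraction)
  keys <- unique(fr[, c("site", "strain")])
  aggregates <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    v <- site_fractions(fr, keys$site[i], keys$strain[i])
    data.frame(site = keys$site[i], strain = keys$strain[i],
               total_methylated_pct = 100 * sum(v[names(v) %in% c("me1", "me2", "me3")]),
               unmodified_pct = 100 * sum(v[names(v) %in% c("me0", "unmod")]))
  }))
  sites <- unique(fr$site)
  comparison <- do.call(rbind, lapply(sites, function(s) {
    has_a <- any(fr$site == s & fr$strain == strain_a)
    has_b <- any(fr$site == s & fr$strain == strain_b)
    if (!has_a || !has_b) return(NULL)
    fa <- site_fractions(fr, s, strain_a)
    fb <- site_fractions(fr, s, strain_b)
    forms <- intersect(names(fb), names(fa))
    data.frame(site = s, form = forms,
               pct_a = 100 * unname(fa[forms]), pct_b = 100 * unname(fb[forms]),
               absolute_pp = 100 * (unname(fa[forms]) - unname(fb[forms])),
               relative_pct = ifelse(fb[forms] > 0,
                                     100 * (fa[forms] - fb[forms]) / fb[forms],
                                     Inf))
  }))
  if (!is.null(comparison)) rownames(comparison) <- NULL
  list(fractions = fractions, aggregates = aggregates, comparison = comparison)
}

#' Read a peptide-form TSV (site, form, strain, abundance)
#' @param path input file.
#' @return data.frame suitable for [form_fractions()].
#' @export
read_peptide_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("site", "form", "strain", "abundance")
  if (!all(need %in% names(tab)))
    stop("peptide table needs columns: ", paste(need, collapse = ", "))
  tab
}
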