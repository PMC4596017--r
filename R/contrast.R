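#' Gray/white image contrast per subject and lobe
#'
#' `C = (wm_intensity - gm_intensity) / gm_intensity`, computed rowwise.
#' C is dimensionless and scale-invariant: multiplying both intensities
#' by any positive constant leaves it unchanged.
#'
#' @param table data.frame with columns `subject_id`, `lobe`,
#'   `gm_intensity`, `wm_intensity`.
#' @return data.frame with columns `subject_id`, `lobe`, `C`.
#' @export
compute_contrast <- function(table) {
  req <- c("subject_id", "lobe", "gm_intensity", "wm_intensity")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("intensity table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(table$gm_intensity <= 0))
    stop("nonpositive gray matter intensity; contrast is undefined")
  data.frame(subject_id = table$subject_id, lobe = table$lobe,
             C = (table$wm_intensity - table$gm_intensity) /
               table$gm_intensity,
             stringsAsFactors = FALSE)
}

#' Site and age effects on image contrast
#'
#' Per lobe, fits `C ~ site + age` (site as one indicator per site, age
#' mean-centered within the modeled sample) and reports the partial F
#' statistic for site (adjusting for age) and for age (adjusting for
#' site). P values are uncorrected for multiple comparisons and flagged
#' as such. Scope is either the full sample or a single age bin.
#'
#' @param contrast data.frame from [compute_contrast()].
#' @param records Participant table (columns `subject_id`, `age`,
#'   `site`, `age_bin`).
#' @param scope `"full"` or an age-bin number.
#' @return data.frame with columns `lobe`, `scope`, `effect`, `F`,
#'   `df1`, `df2`, `p`, `p_adjustment` (`"uncorrected"`).
#' @export
contrast_anova <- function(contrast, records, scope = "full") {
  dat <- merge(contrast, records, by = "subject_id")
  if (!identical(scope, "full")) {
    dat <- dat[dat$age_bin == as.integer(scope), , drop = FALSE]
  }
  out <- list()
  for (lobe in unique(dat$lobe)) {
    d <- dat[dat$lobe == lobe, , drop = FALSE]
    sites <- sort(unique(d$site))
    if (length(sites) < 2L)
      stop("scope '", scope, "' contains a single site; the site effect ",
           "is not estimable")
    S <- outer(d$site, sites, "==") * 1
    colnames(S) <- paste0("site:", sites)
    age <- d$age - mean(d$age)
    y <- matrix(d$C, ncol = 1L)
    X_full <- cbind(S, age = age)
    X_no_age <- S
    X_no_site <- cbind(intercept = 1, age = age)
    site_f <- partial_f(y, X_full, X_no_site)
    age_f <- partial_f(y, X_full, X_no_age)
    out[[lobe]] <- data.frame(
      lobe = lobe, scope = as.character(scope),
      effect = c("site", "age"),
      F = c(site_f$F, age_f$F),
      df1 = c(site_f$df1, age_f$df1),
      df2 = c(site_f$df2, age_f$df2),
      p = c(site_f$p, age_f$p),
      p_adjustment = "uncorrected",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
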