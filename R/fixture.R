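#' Packaged lesion-count fixture table
#'
#' Builds the 322-lesion label table whose marginal and joint counts equal
#' every count printed for the study cohort: 153 gadolinium-enhancing lesions
#' (61 ring, 92 nodular; 137 QSM-positive), 169 non-enhancing lesions split
#' into the four positivity subtypes (114 doubly positive, 16 exchange-rate
#' positive only, 31 susceptibility positive only, 8 doubly negative), and
#' overall totals of 261 exchange-rate-positive and 282
#' susceptibility-positive lesions (which fixes the enhancing lesions'
#' exchange-rate-positive count at 131).
#'
#' Cells the cohort report does not print are filled deterministically: the
#' exchange-rate-positive enhancing lesions are all taken to be
#' QSM-positive (maximal overlap), and QSM ring shapes are assigned at the
#' gadolinium ring fraction (0.399) within each QSM-positive group.
#' Construction is self-checked against every printed count and errors if
#' any sum fails to close.
#'
#' @param n_patients Number of patient ids to cycle lesions over.
#'
#' @return Tibble with one row per lesion: `lesion_id`, `patient_id`,
#'   `gd_positive`, `gd_shape`, `kex_positive`, `qsm_positive`, `qsm_shape`.
#' @export
#' @examples
#' fx <- lesion_fixture()
#' nrow(fx)            # 322
#' sum(fx$kex_positive)  # 261
lesion_fixture <- function(n_patients = 30) {
  ring_frac <- 61 / 153

  block <- function(n, gd, gd_shape, kex, qsm) {
    if (n == 0) return(NULL)
    tibble::tibble(gd_positive = gd, gd_shape = gd_shape,
                   kex_positive = kex, qsm_positive = qsm)[rep(1, n), ]
  }
  qsm_shapes <- function(n) {
    n_ring <- round(n * ring_frac)
    rep(c("ring", "nodular"), c(n_ring, n - n_ring))
  }

  # Gd+ (153): kex+ = 131, QSM+ = 137; kex+ nested in QSM+.
  # Ring/nodular Gd shape assigned proportionally within each cell.
  gd_cells <- list(
    block(131, TRUE, NA_character_, TRUE, TRUE),   # kex+ qsm+
    block(6,   TRUE, NA_character_, FALSE, TRUE),  # kex- qsm+
    block(16,  TRUE, NA_character_, FALSE, FALSE)  # kex- qsm-
  )
  gd_tbl <- dplyr::bind_rows(gd_cells)
  gd_tbl$gd_shape <- rep(c("ring", "nodular"), c(61, 92))

  # Gd- (169): the four positivity subtypes
  gdneg_tbl <- dplyr::bind_rows(
    block(114, FALSE, "none", TRUE, TRUE),
    block(16,  FALSE, "none", TRUE, FALSE),
    block(31,  FALSE, "none", FALSE, TRUE),
    block(8,   FALSE, "none", FALSE, FALSE)
  )

  tbl <- dplyr::bind_rows(gd_tbl, gdneg_tbl)
  tbl$qsm_shape <- "none"
  tbl$qsm_shape[tbl$qsm_positive] <- unlist(
    tapply(seq_len(nrow(tbl))[tbl$qsm_positive],
           tbl$gd_positive[tbl$qsm_positive],
           function(i) qsm_shapes(length(i)), simplify = FALSE),
    use.names = FALSE
  )
  tbl <- tibble::add_column(tbl,
                            lesion_id = seq_len(nrow(tbl)),
                            patient_id = rep_len(seq_len(n_patients), nrow(tbl)),
                            .before = 1)
  check_fixture(tbl)
  tbl
}

# every printed count must close; construction error otherwise
check_fixture <- function(tbl) {
  gp <- tbl$gd_positive; kp <- tbl$kex_positive; qp <- tbl$qsm_positive
  checks <- c(
    total = nrow(tbl) == 322,
    gd_pos = sum(gp) == 153,
    gd_neg = sum(!gp) == 169,
    gd_ring = sum(tbl$gd_shape == "ring", na.rm = TRUE) == 61,
    gd_nodular = sum(tbl$gd_shape == "nodular", na.rm = TRUE) == 92,
    gd_qsm_pos = sum(gp & qp) == 137,
    kex_total = sum(kp) == 261,
    qsm_total = sum(qp) == 282,
    p1 = sum(!gp & kp & qp) == 114,
    p2a = sum(!gp & kp & !qp) == 16,
    p2b = sum(!gp & !kp & qp) == 31,
    p3 = sum(!gp & !kp & !qp) == 8,
    gdneg_kex = sum(!gp & kp) == 130,
    gdneg_qsm = sum(!gp & qp) == 145,
    shape_iff_qsm = all((tbl$qsm_shape != "none") == qp)
  )
  stop_if(!all(checks),
          paste("fixture self-check failed:",
                paste(names(checks)[!checks], collapse = ", ")))
  invisible(tbl)
}
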