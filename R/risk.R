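# Joins the lodging and fertility mesh tables, quantifies the inside-mesh
# SAN-inclination relationship, converts fertilizer N to a soil
# concentration, and emits the absorbable-nitrogen risk map.

#' Join the lodging and fertility mesh tables
#'
#' Inner join on \code{mesh_id}; cells missing the inclination angle or the
#' SAN estimate are dropped, with the dropped count attached as attribute
#' \code{"dropped"} and reported via \code{message()}.
#'
#' @param lodging output of \code{\link{lodgingMeshMap}}
#' @param fertility output of \code{\link{fertilityMeshMap}}
#' @return data.frame: mesh_id, x, y, theta, level, delta_chm, san_est,
#'   is_edge
#' @export
joinMesh <- function(lodging, fertility) {
  shared <- intersect(lodging$mesh_id, fertility$mesh_id)
  if (!length(shared))
    stop("disjoint grids: no shared mesh_id", call. = FALSE)
  l <- lodging[match(shared, lodging$mesh_id), ]
  f <- fertility[match(shared, fertility$mesh_id), ]
  if (any(l$is_edge != f$is_edge))
    stop("edge flags disagree: the two tables come from different grids",
         call. = FALSE)
  out <- data.frame(mesh_id = shared, x = l$x, y = l$y,
                    theta = l$theta, level = l$level,
                    delta_chm = l$delta_chm, san_est = f$san_est,
                    is_edge = l$is_edge)
  keep <- !is.na(out$theta) & !is.na(out$san_est)
  dropped <- sum(!keep) + length(unique(c(lodging$mesh_id,
                                          fertility$mesh_id))) -
    length(shared)
  out <- out[keep, ]
  rownames(out) <- NULL
  if (dropped > 0)
    message(dropped, " mesh cell(s) dropped (missing in one table or ",
            "missing a value)")
  attr(out, "dropped") <- dropped
  out
}

#' Inside-mesh correlation between SAN and inclination angle
#'
#' Pearson correlation and the OLS line of theta on SAN over inside cells
#' only; edge cells — which lodge from fertilizer overlap regardless of SAN —
#' are counted but excluded from the correlation.
#'
#' @param joined output of \code{\link{joinMesh}}
#' @return list: nTotal, nInside, nEdge, insideFraction, pearsonRInside,
#'   intercept, slope (theta on SAN)
#' @export
correlateInside <- function(joined) {
  inside <- joined[!joined$is_edge, ]
  if (nrow(inside) < 3L)
    stop("need >= 3 inside cells", call. = FALSE)
  if (stats::sd(inside$san_est) == 0 || stats::sd(inside$theta) == 0)
    stop("undefined correlation: constant variable on inside cells",
         call. = FALSE)
  fit <- stats::lm(theta ~ san_est, data = inside)
  list(nTotal = nrow(joined),
       nInside = nrow(inside),
       nEdge = sum(joined$is_edge),
       insideFraction = nrow(inside) / nrow(joined),
       pearsonRInside = stats::cor(inside$san_est, inside$theta),
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}

#' Convert a fertilizer-N rate to a soil concentration
#'
#' Distributes the applied nitrogen over the tillage layer:
#' rate / (10 * depth * bulkDensity). The reference application of
#' 70 kg N ha^-1 over a 0.1 m layer at 1.0 Mg m^-3 corresponds to
#' 70 mg N kg^-1.
#'
#' @param rate fertilizer rate, kg N ha^-1
#' @param depth tillage depth, m
#' @param bulkDensity soil bulk density, Mg m^-3
#' @return concentration, mg N kg^-1
#' @examples
#' fertilizerToSoilN(70, 0.1, 1.0)  # 70
#' @export
fertilizerToSoilN <- function(rate, depth = 0.1, bulkDensity = 1.0) {
  if (rate < 0 || depth <= 0 || bulkDensity <= 0)
    stop("rate must be >= 0; depth and bulk density must be > 0",
         call. = FALSE)
  rate / (10 * depth * bulkDensity)
}

#' Absorbable nitrogen
#'
#' SAN plus fertilizer-derived nitrogen on the same mg N kg^-1 soil basis.
#'
#' @param sanEst estimated SAN, mg N kg^-1
#' @param fert fertilizer-derived concentration, mg N kg^-1
#' @return mg N kg^-1
#' @export
absorbableN <- function(sanEst, fert) {
  if (any(sanEst < 0, na.rm = TRUE) || any(fert < 0))
    stop("inputs must be non-negative", call. = FALSE)
  sanEst + fert
}

#' Absorbable-nitrogen lodging-risk map
#'
#' Per-cell absorbable N and risk flags: \code{lodging_possible} where the
#' SAN estimate reaches the lodging onset (140 mg N kg^-1 by default),
#' \code{above_guideline} where absorbable N reaches the guideline
#' (200 mg N kg^-1 by default); a separate \code{edge_caution} flag marks
#' edge cells, which lodge from fertilizer overlap regardless of SAN and are
#' never folded into the SAN-based flags.
#'
#' @param joined output of \code{\link{joinMesh}}
#' @param fert fertilizer-derived concentration, mg N kg^-1
#' @param onset lodging-onset SAN, mg N kg^-1
#' @param guideline absorbable-N guideline, mg N kg^-1
#' @return data.frame: mesh_id, x, y, san_est, theta, level, is_edge,
#'   absorbable_n, lodging_possible, above_guideline, edge_caution,
#'   risk_flag ("ok", "lodging_possible", "above_guideline")
#' @export
riskMap <- function(joined, fert, onset = 140, guideline = 200) {
  if (onset <= 0 || guideline <= 0)
    stop("thresholds must be positive", call. = FALSE)
  an <- absorbableN(pmax(joined$san_est, 0), fert)
  lodg <- joined$san_est >= onset
  above <- an >= guideline
  data.frame(mesh_id = joined$mesh_id, x = joined$x, y = joined$y,
             san_est = joined$san_est, theta = joined$theta,
             level = joined$level, is_edge = joined$is_edge,
             absorbable_n = an,
             lodging_possible = lodg,
             above_guideline = above,
             edge_caution = joined$is_edge,
             risk_flag = ifelse(above, "above_guideline",
                                ifelse(lodg, "lodging_possible", "ok")))
}
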