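# Resource selection functions: used/available point designs at the
# owner-buffer and home-range scales, per-habitat binomial mixed models
# (logit link, animal random intercept), and the use/availability
# proportion summary.

.sample_in_boundary <- function(n, boundary, landscape, exclude,
                                max_iter = 1000) {
  # rejection-sample n uniform points inside the boundary whose land cover
  # is not excluded
  if (boundary$type == "disc") {
    bbox <- c(boundary$x - boundary$radius, boundary$x + boundary$radius,
              boundary$y - boundary$radius, boundary$y + boundary$radius)
  } else {
    bbox <- c(range(boundary$ring[, 1]), range(boundary$ring[, 2]))
  }
  ext <- landscape_extent(landscape)
  bbox[1] <- max(bbox[1], ext["xmin"]); bbox[2] <- min(bbox[2], ext["xmax"])
  bbox[3] <- max(bbox[3], ext["ymin"]); bbox[4] <- min(bbox[4], ext["ymax"])
  xs <- ys <- cs <- NULL
  got <- 0L
  for (it in seq_len(max_iter)) {
    m <- max(2L * (n - got), 100L)
    px <- stats::runif(m, bbox[1], bbox[2])
    py <- stats::runif(m, bbox[3], bbox[4])
    inside <- if (boundary$type == "disc") {
      (px - boundary$x)^2 + (py - boundary$y)^2 <= boundary$radius^2
    } else {
      point_in_convex(px, py, boundary$ring)
    }
    px <- px[inside]; py <- py[inside]
    if (!length(px)) next
    cat_ <- landscape_category(landscape, px, py)
    ok <- !(cat_ %in% exclude)
    px <- px[ok]; py <- py[ok]; cat_ <- cat_[ok]
    take <- min(length(px), n - got)
    if (take > 0) {
      xs <- c(xs, px[seq_len(take)]); ys <- c(ys, py[seq_len(take)])
      cs <- c(cs, cat_[seq_len(take)])
      got <- got + take
    }
    if (got >= n) break
  }
  if (got < n) return(NULL)   # boundary effectively empty after exclusions
  data.frame(x = xs, y = ys, habitat = cs, stringsAsFactors = FALSE)
}

#' Build a used/available RSF design
#'
#' Used points are the cleaned fixes with land cover attached; available
#' points are drawn uniformly (rejection sampling) inside each animal's
#' boundary -- a disc centred on the owner's home or the 100% MCP polygon.
#' Points in excluded categories (undifferentiated, water) are dropped from
#' BOTH sets, and availables are re-drawn so the available:used ratio per
#' animal is exactly `ratio`.
#'
#' @param fixes cleaned fixes `(animal_id, t, x, y)`.
#' @param boundaries named list per animal: either
#'   `list(type = "disc", x =, y =, radius =)` or
#'   `list(type = "polygon", ring = matrix)` (convex).
#' @param landscape a `roam_landscape`.
#' @param ratio available points per used point (default 10).
#' @param seed integer; same seed, same available points.
#' @param scale label stored on the rows (`"owner_buffer"` or `"mcp"`).
#' @param exclude categories removed from both sets.
#' @return data.frame of class `rsf_design`:
#'   `(animal_id, x, y, used, habitat, scale)`.
#' @export
build_design <- function(fixes, boundaries, landscape, ratio = 10,
                         seed = 1, scale = "mcp",
                         exclude = ROAM_EXCLUDED_CATEGORIES) {
  set.seed(seed)
  ids <- unique(fixes$animal_id)
  rows <- list()
  for (id in ids) {
    tr <- fixes[fixes$animal_id == id, , drop = FALSE]
    b <- boundaries[[id]]
    if (is.null(b)) {
      warning("no boundary for animal ", id, "; dropped")
      next
    }
    inside <- if (b$type == "disc") {
      (tr$x - b$x)^2 + (tr$y - b$y)^2 <= b$radius^2
    } else {
      point_in_convex(tr$x, tr$y, b$ring)
    }
    tr <- tr[inside, , drop = FALSE]
    if (!nrow(tr)) {
      warning("animal ", id, " has no fixes inside its boundary; dropped")
      next
    }
    hab <- landscape_category(landscape, tr$x, tr$y)
    keep <- !(hab %in% exclude)
    tr <- tr[keep, , drop = FALSE]; hab <- hab[keep]
    if (!nrow(tr)) {
      warning("animal ", id, " has no usable fixes after category ",
              "exclusions; dropped")
      next
    }
    avail <- .sample_in_boundary(ratio * nrow(tr), b, landscape, exclude)
    if (is.null(avail)) {
      warning("boundary of animal ", id, " has no usable area after ",
              "exclusions; dropped")
      next
    }
    rows[[length(rows) + 1L]] <- rbind(
      data.frame(animal_id = id, x = tr$x, y = tr$y, used = 1L,
                 habitat = hab, scale = scale, stringsAsFactors = FALSE),
      data.frame(animal_id = id, x = avail$x, y = avail$y, used = 0L,
                 habitat = avail$habitat, scale = scale,
                 stringsAsFactors = FALSE))
  }
  if (!length(rows)) stop("no animal yielded a usable design")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rsf_design", class(out))
  out
}

#' Fit the selection model for one habitat type
#'
#' Binomial GLMM with logit link: the used/available indicator regressed on
#' a binary in-habitat indicator (1 = point in the habitat type) with a
#' per-animal random intercept, fitted by Laplace-approximated ML
#' ([lme4::glmer]). The selection coefficient is the in-habitat log-odds
#' contrast: positive = selection, negative = avoidance. When the
#' random-intercept variance collapses to the boundary, `fallback = TRUE`
#' refits a plain logistic model with cluster-robust (per-animal) standard
#' errors instead.
#'
#' @param design an `rsf_design`.
#' @param habitat habitat category name.
#' @param ci_level Wald CI level (default 0.95).
#' @param fallback use the fixed-effects fallback at the zero-variance
#'   boundary.
#' @return one-row data.frame `(habitat, beta, se, lower, upper, p,
#'   ranef_var, n_used, n_avail, model)`.
#' @export
fit_habitat_model <- function(design, habitat, ci_level = 0.95,
                              fallback = FALSE) {
  if (!habitat %in% design$habitat)
    stop("habitat absent from design: ", habitat)
  if (length(unique(design$animal_id)) < 2)
    stop("need >= 2 animals for a random-intercept model")
  d <- data.frame(used = design$used,
                  inhab = as.integer(design$habitat == habitat),
                  animal_id = design$animal_id)
  tab <- table(d$inhab, d$used)
  if (nrow(tab) < 2)
    stop("in-habitat indicator is constant for ", habitat)
  if (any(tab == 0))
    stop("separation: habitat ", habitat, " perfectly predicts use; ",
         "consider a penalized fit")
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  fit <- suppressMessages(lme4::glmer(
    used ~ inhab + (1 | animal_id), data = d, family = stats::binomial(),
    control = lme4::glmerControl(calc.derivs = FALSE,
                                 check.conv.singular = "ignore")))
  vr <- as.numeric(lme4::VarCorr(fit)$animal_id[1])
  if (fallback && vr < 1e-8) {
    gfit <- stats::glm(used ~ inhab, data = d, family = stats::binomial())
    vc <- sandwich::vcovCL(gfit, cluster = d$animal_id)
    beta <- stats::coef(gfit)["inhab"]
    se <- sqrt(vc["inhab", "inhab"])
    model <- "glm+clustered"
  } else {
    beta <- lme4::fixef(fit)["inhab"]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
    model <- "glmm"
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  data.frame(habitat = habitat, beta = unname(beta), se = unname(se),
             lower = unname(beta - z * se), upper = unname(beta + z * se),
             p = unname(p), ranef_var = vr,
             n_used = sum(d$used == 1), n_avail = sum(d$used == 0),
             model = model, stringsAsFactors = FALSE)
}

#' Run the full habitat-selection analysis
#'
#' Builds used/available designs at both scales (a disc of
#' `config$owner_buffer_radius` around each owner's home, and each animal's
#' 100% MCP), fits the per-habitat selection models, and tabulates used and
#' available habitat proportions.
#'
#' @param fixes cleaned fixes.
#' @param owner_homes named list / data.frame lookup `animal_id -> (x, y)`
#'   of owner-home coordinates.
#' @param landscape a `roam_landscape`.
#' @param config a [roam_config()].
#' @param habitats habitat categories to fit (default: the non-excluded
#'   categories present in the design).
#' @return list per scale: `design`, `coefficients` (Table-4-style
#'   data.frame), `proportions` (data.frame habitat x used/available
#'   fractions).
#' @export
run_rsf <- function(fixes, owner_homes, landscape, config = roam_config(),
                    habitats = NULL) {
  ids <- unique(fixes$animal_id)
  disc_bounds <- list(); mcp_bounds <- list()
  for (id in ids) {
    tr <- fixes[fixes$animal_id == id, , drop = FALSE]
    hm <- owner_homes[[id]]
    if (!is.null(hm))
      disc_bounds[[id]] <- list(type = "disc", x = hm[1], y = hm[2],
                                radius = config$owner_buffer_radius)
    hull <- tryCatch(mcp(tr, animal_id = id)$polygons[[1]],
                     error = function(e) NULL)
    if (!is.null(hull))
      mcp_bounds[[id]] <- list(type = "polygon", ring = hull)
  }
  scales <- list(owner_buffer = disc_bounds, mcp = mcp_bounds)
  out <- list()
  for (sc in names(scales)) {
    design <- build_design(fixes, scales[[sc]], landscape,
                           ratio = config$avail_ratio,
                           seed = config$rng_seed, scale = sc)
    habs <- if (is.null(habitats))
      setdiff(sort(unique(design$habitat)), ROAM_EXCLUDED_CATEGORIES)
    else habitats
    coefs <- do.call(rbind, lapply(habs, function(h) {
      tryCatch(fit_habitat_model(design, h, config$ci_level_rsf),
               error = function(e) {
                 warning("habitat ", h, " not fitted at scale ", sc, ": ",
                         conditionMessage(e))
                 NULL
               })
    }))
    prop <- do.call(rbind, lapply(split(design$habitat, design$used),
                                  function(h) prop.table(table(
                                    factor(h, levels = habs)))))
    proportions <- data.frame(habitat = habs,
                              available = as.numeric(prop["0", ]),
                              used = as.numeric(prop["1", ]))
    out[[sc]] <- list(design = design, coefficients = coefs,
                      proportions = proportions)
  }
  out
}
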