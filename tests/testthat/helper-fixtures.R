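# fixture builders: all charts are constructed in code at test time

SITE6 <- c("MB", "B", "DB", "ML", "L", "DL")
DEFAULT_PRESENT <- setdiff(1:32, c(1, 16, 17, 32))

healthy_sites <- function(bop_sites = character()) {
  lapply(SITE6, function(id) {
    site_measurement(id, pd = 2, rec = -2, bop = id %in% bop_sites)
  })
}

# build a chart from a base of healthy teeth with targeted site overrides.
# sites: list of list(tooth=, site=, pd=, rec=, bop=, sup=)
# bone / furcation / mobility: named lists tooth -> value
# flags: named list tooth -> character vector
make_chart <- function(sites = list(), present = DEFAULT_PRESENT,
                       implants = integer(), bone = list(),
                       furcation = list(), mobility = list(),
                       flags = list(), age = 40, chart_id = "fixture",
                       bop_sites = list(), ...) {
  profile <- patient_profile(age_years = age, ...)
  teeth <- lapply(1:32, function(tn) {
    key <- as.character(tn)
    if (tn %in% implants) {
      s <- lapply(SITE6, function(id) {
        site_measurement(id, pd = 3, rec = -3,
                         bop = id %in% (bop_sites[[key]] %||% character()))
      })
      return(tooth_record(tn, is_implant = TRUE, sites = s,
                          flags = flags[[key]] %||% character()))
    }
    if (!(tn %in% present)) return(tooth_record(tn, present = FALSE))
    s <- healthy_sites(bop_sites[[key]] %||% character())
    names(s) <- SITE6
    for (ov in sites) {
      if (ov$tooth == tn) {
        s[[ov$site]] <- site_measurement(
          ov$site, pd = ov$pd %||% 2, rec = ov$rec %||% -2,
          bop = ov$bop %||% FALSE, sup = ov$sup %||% FALSE)
      }
    }
    tooth_record(tn, sites = unname(s),
                 bone_loss_percent = bone[[key]] %||% 0,
                 furcation_class = furcation[[key]] %||% 0,
                 mobility_class = mobility[[key]] %||% 0,
                 flags = flags[[key]] %||% character())
  })
  periodontal_chart(chart_id, profile, teeth, exam_date = "2023-03-01")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# interdental breakdown of `cal` mm at the MB site of each tooth in `teeth`;
# pd chosen so stages I/II avoid the complexity shift-up
cal_site <- function(tooth, cal, bop = TRUE) {
  pd <- if (cal <= 4) min(max(cal + 2, 2), 5) else min(cal, 8)
  list(tooth = tooth, site = "MB", pd = pd, rec = cal - pd, bop = bop)
}

perio_fixture <- function(teeth_affected, cal, bone = 30, age = 50, ...) {
  make_chart(sites = lapply(teeth_affected, cal_site, cal = cal),
             bone = stats::setNames(as.list(rep(bone,
                                                length(teeth_affected))),
                                    as.character(teeth_affected)),
             age = age, ...)
}

# random but always-valid chart for fuzzing (seeded by the caller)
random_chart <- function() {
  n_present <- sample(8:28, 1)
  present <- sort(sample(DEFAULT_PRESENT, n_present))
  sites <- list()
  for (tn in sample(present, sample(1:6, 1))) {
    for (sid in sample(SITE6, sample(1:3, 1))) {
      sites[[length(sites) + 1L]] <- list(
        tooth = tn, site = sid, pd = sample(1:9, 1),
        rec = sample(-3:4, 1), bop = sample(c(TRUE, FALSE), 1))
    }
  }
  bone <- as.list(sample(0:70, length(present), replace = TRUE))
  names(bone) <- as.character(present)
  make_chart(sites = sites, present = present, bone = bone,
             age = sample(20:80, 1),
             teeth_lost_to_periodontitis = sample(0:min(4, 32 - n_present),
                                                  1))
}

# independent oracle: two-sided exact signed-rank p by enumerating all 2^n
# sign assignments over the (mid)ranks
wsr_brute_force <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(grid %*% r)
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

stage_rank <- function(stage) match(stage, c("I", "II", "III", "IV"))
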