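# Frozen expected values, computed from the closed forms by direct
# arithmetic (independently of the package code paths they check).

oracle <- list(
  v_sphere_4cm   = 33.51032164,   # (pi/6) * 4^3
  v_sphere_2.7cm = 10.30599470,   # (pi/6) * 2.7^3
  k_gi_2.6       = 2.176260214,   # 3 ln2 / ln 2.6
  v12_4cm_0mm_noncop = 12.06924332,  # closed-form V12, CI 1.0 / GI 2.6 / 15 Gy
  v12_4cm_2mm_cop    = 30.69038168,  # closed-form V12, CI 1.0 / GI 3.1 / 15 Gy
  idp1_4cm_0mm_noncop = 14.50286547, # 12 Gy * (r_c / r_rx)^k, V12 = 10 cm^3
  idp3_4cm_1mm_noncop = 20.94151614, # 19.2 Gy constraint, GI 2.5, CI 1.0
  t3_iso  = 19.16960076,          # total dose, BED 60 Gy in 3 fx at a/b 3
  beta1   = 0.05589708128,        # TCP slope from the two anchors
  beta0   = -2.209299885,         # TCP intercept
  tcp_14gy = 0.374313659          # logistic at BED12 = 14 * (1 + 14/12)
)

# benchmark quality rows used repeatedly in tests
quality_4_0_noncop <- function() plan_quality(112, 97, 1.0, 2.6)
quality_4_2_cop    <- function() plan_quality(134, 107, 1.0, 3.1)

# iterate over every benchmark configuration
for_each_config <- function(fn, margins = c(0, 1, 2),
                            beams = c("coplanar", "noncoplanar")) {
  tab <- plan_quality_table()
  for (b in beams) for (m in margins) for (d in seq(0.5, 4, by = 0.5)) {
    q <- lookup_plan_quality(tab, d, m, b)
    fn(d, m, b, q)
  }
  invisible(NULL)
}
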