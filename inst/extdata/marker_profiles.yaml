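# Built-in latent marker profiles (version 1).
# Each profile is a mixture of logit-normal components on the 0-100% scale
# (spread on the logit scale; spread 0 = point mass) plus an atom of truly
# negative (0%) cases. Calibrated by Monte Carlo to the marker-typical
# median / interquartile-range pairs of multi-rater breast panels:
# ER 95 (30) CNB / 95 (15) EXC, PR 60 (89) / 73 (95), Ki67 20 (85) / 10 (20).
# Only the median/IQR level is calibrated; per-observer bias magnitudes in
# the observer model are order-of-magnitude defaults, not fitted values.
version: 1
profiles:
  er_cnb:
    name: er_cnb
    negative_mass: 0.12
    components:
      - {weight: 0.28, location: 100, spread: 0.0}
      - {weight: 0.43, location: 95,  spread: 0.9}
      - {weight: 0.17, location: 45,  spread: 1.2}
  er_exc:
    name: er_exc
    negative_mass: 0.10
    components:
      - {weight: 0.28, location: 100, spread: 0.0}
      - {weight: 0.50, location: 95,  spread: 0.9}
      - {weight: 0.12, location: 70,  spread: 1.0}
  pr_cnb:
    name: pr_cnb
    negative_mass: 0.18
    components:
      - {weight: 0.12, location: 100, spread: 0.0}
      - {weight: 0.30, location: 90,  spread: 1.0}
      - {weight: 0.23, location: 50,  spread: 1.2}
      - {weight: 0.17, location: 6,   spread: 1.0}
  pr_exc:
    name: pr_exc
    negative_mass: 0.20
    components:
      - {weight: 0.13, location: 100, spread: 0.0}
      - {weight: 0.37, location: 92,  spread: 1.0}
      - {weight: 0.18, location: 50,  spread: 1.2}
      - {weight: 0.12, location: 4,   spread: 1.0}
  ki67_cnb:
    name: ki67_cnb
    negative_mass: 0.0
    components:
      - {weight: 0.33, location: 3,  spread: 0.8}
      - {weight: 0.32, location: 20, spread: 0.8}
      - {weight: 0.35, location: 90, spread: 0.9}
  ki67_exc:
    name: ki67_exc
    negative_mass: 0.0
    components:
      - {weight: 0.40, location: 5,  spread: 0.8}
      - {weight: 0.34, location: 13, spread: 0.7}
      - {weight: 0.26, location: 42, spread: 1.1}
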