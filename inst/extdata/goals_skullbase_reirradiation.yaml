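# Clinical goals and dose constraints for skull-base SBRT reirradiation,
# for the 21-27 Gy / 3-fraction and 40-45 Gy / 5-fraction regimes.
# Dmax means the dose to the hottest 0.01 cm3; percent thresholds are
# relative to the prescription dose. Advisory entries are reported but are
# never pass/fail (as low as reasonably achievable when outside of or away
# from the target).
goals:
  - structure: PTV
    goal: "V100% > 95%"
  - structure: PTV
    goal: "Dmax < 120%"
  - structure: Brainstem
    goal: "Dmax < 10 Gy"
    fractions: 3
  - structure: Brainstem
    goal: "Dmax < 13 Gy"
    fractions: 5
  - structure: Spinal cord
    goal: "Dmax < 9 Gy"
    fractions: 3
  - structure: Spinal cord
    goal: "Dmax < 12 Gy"
    fractions: 5
  - structure: Optic apparatus
    goal: "Dmax < 9 Gy"
    fractions: 3
  - structure: Optic apparatus
    goal: "Dmax < 12 Gy"
    fractions: 5
  - structure: Carotids
    goal: "Dmax < 20 Gy"
    fractions: 3
  - structure: Carotids
    goal: "Dmax < 30 Gy"
    fractions: 5
  - structure: Cochlea
    goal: "Dmax < 21 Gy"
    fractions: 3
  - structure: Cochlea
    goal: "Dmax < 21 Gy"
    fractions: 5
  - structure: Temporal lobe
    goal: "Dmax < 18 Gy"
    fractions: 3
  - structure: Temporal lobe
    goal: "V12 Gy < 3 cm3"
    fractions: 3
  - structure: Temporal lobe
    goal: "Dmax < 27 Gy"
    fractions: 5
  - structure: Temporal lobe
    goal: "V18 Gy < 3 cm3"
    fractions: 5
  - structure: Brainstem
    goal: "Dmean < 5 Gy"
    advisory: true
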