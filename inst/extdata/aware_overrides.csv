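source_name,reference_name
Flucloxacillin sodium,Flucloxacillin
Flucloxacillin magnesium,Flucloxacillin
Doxycycline hyclate,Doxycycline
Doxycycline monohydrate,Doxycycline
Erythromycin ethylsuccinate,Erythromycin
Erythromycin stearate,Erythromycin
Pivmecillinam hydrochloride,Pivmecillinam
Minocycline hydrochloride,Minocycline
Ciprofloxacin hydrochloride,Ciprofloxacin
Tetracycline hydrochloride,Tetracycline
Oxytetracycline dihydrate,Oxytetracycline
Vancomycin hydrochloride,Vancomycin
Clindamycin hydrochloride,Clindamycin
Gentamicin sulfate,Gentamicin
Fosfomycin trometamol,Fosfomycin
Sodium fusidate,Fusidic acid
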