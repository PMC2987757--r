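scenario,year,population
moderate,2008,44366332
moderate,2009,44642180.085207246
moderate,2010,44919743.258470744
moderate,2011,45199032.183366537
moderate,2012,45480057.589771613
moderate,2013,45762830.274276026
moderate,2014,46047361.100597739
moderate,2015,46333661
moderate,2016,46499419.190676585
moderate,2017,46665770.379557572
moderate,2018,46832716.688087873
moderate,2019,47000260.245301858
moderate,2020,47168403.187850468
moderate,2021,47337147.660028517
moderate,2022,47506495.813802004
moderate,2023,47676449.808835573
moderate,2024,47847011.81252002
moderate,2025,48018184
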